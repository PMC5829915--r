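make_spot_frame <- function(optics, xy_nm, totals) {
  frame <- matrix(0, optics$image_shape[1], optics$image_shape[2])
  for (i in seq_len(nrow(xy_nm)))
    frame <- nm2motility:::add_spot(frame, xy_nm[i, 1], xy_nm[i, 2],
                                    totals[i], optics)
  frame
}

test_that("background subtraction recovers offsets and clips at zero", {
  opt <- test_optics(frame_count = 4, shape = c(32, 32))
  const <- function(v, nf) {
    structure(list(channels = list("488" = array(v, c(32, 32, nf))),
                   optics = opt, truth = NULL, seed = 1),
              class = "movie_stack")
  }
  # subtracting a stack's own mean from a constant stack gives all zeros
  out <- subtract_background(const(7, 4), const(7, 2))
  expect_true(all(out$channels[["488"]] == 0))

  # constant offset c with background mean c recovers the original signal
  opt2 <- test_optics(frame_count = 2, shape = c(32, 32))
  sig <- array(stats::runif(32 * 32 * 2, 0, 50), c(32, 32, 2))
  mv <- const(0, 2); mv$channels[["488"]] <- sig + 13
  out <- subtract_background(mv, const(13, 3))
  expect_equal(out$channels[["488"]], sig, tolerance = 1e-12)

  bad <- const(1, 2); names(bad$channels) <- "561"
  expect_error(subtract_background(const(1, 2), bad), "lacks channel")
})

test_that("LoG detection finds isolated spots, merges unresolved pairs and ignores blanks", {
  opt <- test_optics()
  # blank background-subtracted frame at the default threshold: no spots
  set.seed(50)
  blank <- matrix(pmax(0, stats::rpois(96 * 96, opt$background_mean) -
                         opt$background_mean), 96, 96)
  expect_equal(nrow(detect_spots(blank, opt)), 0)

  # one high-SNR spot: exactly one detection, position error < 1 px
  xy <- matrix(c(5000, 6000), 1)
  s <- detect_spots(make_spot_frame(opt, xy, 3000), opt)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$x_nm - 5000) / opt$pixel_size_nm, 1)
  expect_lt(abs(s$y_nm - 6000) / opt$pixel_size_nm, 1)
  # quality estimates the integrated spot counts
  expect_equal(s$quality, 3000, tolerance = 0.15)
  expect_equal(s$total_intensity, 3000, tolerance = 0.1)

  # two spots 3 um apart resolve; 200 nm apart merge at the 1 um blob scale
  far <- rbind(c(3000, 3000), c(6000, 3000))
  expect_equal(nrow(detect_spots(make_spot_frame(opt, far, c(3000, 3000)),
                                 opt)), 2)
  near <- rbind(c(5000, 5000), c(5200, 5000))
  expect_equal(nrow(detect_spots(make_spot_frame(opt, near, c(3000, 3000)),
                                 opt)), 1)
})

test_that("LAP frame-to-frame matching is optimal against brute-force enumeration", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    xy1 <- matrix(stats::runif(2 * n, 0, 3000), n)
    xy2 <- matrix(stats::runif(2 * m, 0, 3000), m)
    cap <- 1000
    match <- nm2motility:::lap_match(xy1, xy2, cap)
    d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
    linked <- which(!is.na(match))
    cost <- sum(d2[cbind(linked, match[linked])]) +
      (n - length(linked)) * cap^2 + (m - length(linked)) * cap^2
    expect_equal(cost, brute_match_cost(xy1, xy2, cap), tolerance = 1e-6)
  }
})

test_that("linking builds tracks, closes gaps and is permutation invariant", {
  opt <- test_optics()
  mk <- function(frames, xs, ys) {
    data.frame(frame = frames, x_nm = xs, y_nm = ys,
               total_intensity = 1000, mean_intensity = 10,
               radius_nm = 500, quality = 500)
  }
  # single persistent spot: one track with all spots
  sp <- mk(0:9, seq(1000, 1900, by = 100), rep(2000, 10))
  tr <- link_tracks(sp)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  # spot missing for one frame, reappearing 300 nm away: one closed gap
  sp <- mk(c(0, 1, 3, 4), c(1000, 1100, 1400, 1500), rep(2000, 4))
  tr <- link_tracks(sp)
  expect_equal(length(unique(tr$track_id)), 1)

  # gap beyond the frame cap stays split
  sp <- mk(c(0, 1, 6, 7), c(1000, 1100, 1400, 1500), rep(2000, 4))
  tr <- link_tracks(sp, max_frame_gap = 2)
  expect_equal(length(unique(tr$track_id)), 2)

  # two well-separated moving spots; shuffling within-frame order does not
  # change the recovered tracks
  sp2 <- rbind(mk(0:9, seq(1000, 1900, 100), rep(2000, 10)),
               mk(0:9, seq(9000, 8100, -100), rep(7000, 10)))
  canon <- function(tr) {
    unname(lapply(split(tr[order(tr$frame), c("frame", "x_nm", "y_nm")],
                        tr$track_id[order(tr$frame)]),
                  function(d) d[order(d$frame), ]))
  }
  t1 <- canon(link_tracks(sp2))
  set.seed(3)
  t2 <- canon(link_tracks(sp2[sample(nrow(sp2)), ]))
  expect_true(all(vapply(canon(link_tracks(sp2)), function(a)
    any(vapply(t2, function(b) isTRUE(all.equal(a, b, check.attributes = FALSE)),
               logical(1))), logical(1))))
  expect_equal(length(t1), length(t2))
})

test_that("track filtering, kinematics and censoring annotation follow the analysis rules", {
  opt <- optics_model(frame_interval_s = 1)
  lay <- data.frame(segment_id = 1L, x0_nm = 1000, y0_nm = 2000,
                    x1_nm = 21000, y1_nm = 2000, length_um = 20)
  class(lay) <- c("actin_layout", "data.frame")
  mk <- function(frames, xs, ys, id) {
    data.frame(frame = frames, x_nm = xs, y_nm = ys, total_intensity = 1000,
               mean_intensity = 10, radius_nm = 500, quality = 500,
               track_id = id)
  }
  # spot moving exactly 43 nm per 1 s frame for 10 frames
  moving <- mk(0:9, 5000 + 43 * (0:9), rep(2000, 10), 1L)
  stationary <- mk(0:9, rep(9000, 10), rep(2000, 10), 2L)
  tracks <- rbind(moving, stationary)
  class(tracks) <- c("track_table", "data.frame")
  st <- filter_and_annotate(tracks, opt, lay, last_frame = 50)
  expect_equal(nrow(st), 1)   # stationary track dropped by the 150 nm filter
  expect_equal(st$mean_velocity_nm_s, 43, tolerance = 1e-9)
  expect_equal(st$run_length_um, 0.387, tolerance = 1e-9)
  expect_false(st$censored_at_end)
  expect_false(st$censored)

  # track ending within one PSF sigma of the segment end is censored
  ending <- mk(0:9, seq(19000, 20950, length.out = 10), rep(2000, 10), 3L)
  class(ending) <- c("track_table", "data.frame")
  st <- filter_and_annotate(ending, opt, lay, last_frame = 50)
  expect_true(st$censored_at_end)
  expect_true(st$censored)

  # a track running to the final movie frame is censored by the window
  st <- filter_and_annotate(moving_tt <- {
    class(moving) <- c("track_table", "data.frame"); moving
  }, opt, lay, last_frame = 9)
  expect_false(st$censored_at_end)
  expect_true(st$censored)

  # track_statistics on a constructed track
  expect_equal(unname(track_statistics(moving_tt, opt, lay)),
               c(0.387, 43), tolerance = 1e-9)
})

test_that("the default tracking parameters serialize to the standard single-particle tracking settings", {
  p <- trackmate_defaults()
  expect_identical(p$detector, "LoG")
  expect_equal(p$estimated_diameter_nm, 1000)   # 1 um blob diameter
  expect_true(p$quality_threshold >= 50 && p$quality_threshold <= 200)
  expect_identical(p$tracker, "Simple LAP")
  expect_equal(p$linking_max_nm, 1000)          # 1 um linking max
  expect_equal(p$gap_closing_max_nm, 500)       # 0.5 um gap closing
  expect_equal(p$max_frame_gap, 2)
  expect_equal(p$min_displacement_nm, 150)      # displacement filter
})

test_that("two-color ROI intensity measures the second channel at tracked positions", {
  opt <- test_optics(frame_count = 5)
  frames <- lapply(1:5, function(f)
    make_spot_frame(opt, matrix(c(6000, 6000), 1), 2000))
  arr <- array(0, c(96, 96, 5))
  for (f in 1:5) arr[, , f] <- frames[[f]]
  mv <- structure(list(channels = list("561" = arr), optics = opt,
                       truth = NULL, seed = 1), class = "movie_stack")
  tracks <- data.frame(frame = 0:4, x_nm = 6000, y_nm = 6000, track_id = 1L)
  roi <- measure_roi_intensity(mv, tracks, "561", roi_nm = 1000)
  expect_equal(nrow(roi), 1)
  expect_equal(roi$roi_intensity, 2000, tolerance = 0.05)
})
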