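test_that("actin layout is reproducible and follows the length distribution", {
  opt <- test_optics()
  lay1 <- layout_actin(1, length_um_mean = 5, length_um_sd = 0, optics = opt,
                       seed = 4)
  expect_equal(nrow(lay1), 1)
  expect_equal(lay1$length_um, 5)
  d <- sqrt((lay1$x1_nm - lay1$x0_nm)^2 + (lay1$y1_nm - lay1$y0_nm)^2)
  expect_equal(d / 1000, 5, tolerance = 1e-9)

  lay2 <- layout_actin(1, length_um_mean = 5, length_um_sd = 0, optics = opt,
                       seed = 4)
  expect_identical(lay1, lay2)

  big <- optics_model(frame_count = 10, image_shape = c(512, 512))
  lay <- layout_actin(50, length_um_mean = 10, length_um_sd = 2, optics = big,
                      seed = 9)
  se <- 2 / sqrt(50)
  expect_lt(abs(mean(lay$length_um) - 10), 3 * se + 0.2)  # truncation shift

  expect_error(layout_actin(200, length_um_mean = 10, length_um_sd = 0,
                            optics = test_optics(shape = c(32, 32))),
               "too small")
})

test_that("background stacks match the Poisson + read-noise model", {
  opt <- test_optics()
  bg <- render_background_stack(opt, n_frames = 20, seed = 6)
  x <- as.numeric(bg$channels[["488"]])
  se <- sqrt(opt$background_mean + opt$read_noise_sd^2) / sqrt(length(x))
  expect_lt(abs(mean(x) - opt$background_mean), 3 * se + 0.1)
  # variance = Poisson + Gaussian read noise (clipping/rounding adds ~2%)
  expect_lt(abs(stats::var(x) / (opt$background_mean + opt$read_noise_sd^2 + 1/12) - 1),
            0.05)
  bg2 <- render_background_stack(opt, n_frames = 20, seed = 6)
  expect_identical(bg$channels, bg2$channels)
})

test_that("rendering conserves photons and is linear in fluorophore count", {
  opt <- test_optics(frame_count = 60)
  lay <- layout_actin(1, length_um_mean = 6, length_um_sd = 0, optics = opt,
                      seed = 2)
  sp <- default_species()
  cond <- simulation_conditions(max_time_s = 1)  # attach briefly, then gone

  # zero photons: frames are background + read noise only
  opt0 <- test_optics(frame_count = 10,
                      photons_per_fluorophore_per_frame = 1e-9)
  tr0 <- simulate_field(lay, composition = filament_composition(n_motor_molecules_B = 15),
                        species = sp, conditions = simulation_conditions(),
                        optics = opt0, seed = 3)
  mv0 <- render_movie(tr0, seed = 4, actin_channel = NULL)
  x <- as.numeric(mv0$channels[["488"]])
  se <- sqrt(opt0$background_mean + opt0$read_noise_sd^2) / sqrt(length(x))
  expect_lt(abs(mean(x) - opt0$background_mean), 3 * se + 0.1)

  # doubling the labeled-molecule count doubles the summed excess signal
  sticky <- list(A = sp$A,
                 B = motor_species("sticky", 0.999999, 0.19, 8,
                                   unloaded_speed = 0.5, speed_sd = 0))
  render_static <- function(n_mol, seed) {
    comp <- filament_composition(n_motor_molecules_B = n_mol / 2,
                                 distal = c(A = 0, B = n_mol / 2, tail = 0))
    tr <- simulate_field(lay, composition = comp, species = sticky,
                         conditions = simulation_conditions(max_time_s = 1e5),
                         optics = opt, start_window_s = 0, seed = seed)
    mv <- render_movie(tr, seed = seed + 1, actin_channel = NULL)
    sum(mv$channels[["488"]] - opt$background_mean)
  }
  # tolerances: the background-noise SD of the whole-field sum is ~2.5% of
  # the expected signal here, so 3 sigma is ~8% (ratio: ~10%)
  s1 <- render_static(15 * 2, 5)
  s2 <- render_static(30 * 2, 6)
  expect_equal(s2 / s1, 2, tolerance = 0.1)

  # photon conservation: summed excess ~ molecules x photons x frames
  expected <- 30 * opt$photons_per_fluorophore_per_frame * opt$frame_count
  expect_equal(s1 / expected, 1, tolerance = 0.08)
})

test_that("a rendered high-SNR spot sits within 0.1 px of the ground truth centroid", {
  opt <- test_optics(frame_count = 1,
                     photons_per_fluorophore_per_frame = 2000)
  lay <- layout_actin(1, length_um_mean = 6, length_um_sd = 0, optics = opt,
                      seed = 12)
  sp <- default_species()
  sticky <- list(A = sp$A,
                 B = motor_species("sticky", 0.999999, 0.19, 8,
                                   unloaded_speed = 0.1, speed_sd = 0))
  comp <- filament_composition(n_motor_molecules_B = 15)
  tr <- simulate_field(lay, composition = comp, species = sticky,
                       conditions = simulation_conditions(max_time_s = 1e5),
                       optics = opt, start_window_s = 0, seed = 13)
  mv <- render_movie(tr, seed = 14, actin_channel = NULL)
  truth <- tr$positions[1, ]
  frame <- mv$channels[["488"]][, , 1] - opt$background_mean
  # independent centroid oracle around the brightest pixel
  pk <- which(frame == max(frame), arr.ind = TRUE)[1, ]
  w <- 6
  ys <- (pk[1] - w):(pk[1] + w); xs <- (pk[2] - w):(pk[2] + w)
  patch <- pmax(frame[ys, xs], 0)
  cy <- sum(row(patch) * patch) / sum(patch) + ys[1] - 1
  cx <- sum(col(patch) * patch) / sum(patch) + xs[1] - 1
  px <- opt$pixel_size_nm
  expect_lt(abs((cx - 0.5) * px - truth$x_nm) / px, 0.1)
  expect_lt(abs((cy - 0.5) * px - truth$y_nm) / px, 0.1)
})

test_that("movie stacks round-trip through 16-bit TIFF with sidecar metadata", {
  opt <- test_optics(frame_count = 3, shape = c(48, 48))
  bg <- render_background_stack(opt, n_frames = 3, channels = c("488", "561"),
                                seed = 21)
  dir <- withr::local_tempdir()
  write_movie_tiff(bg, dir, "b")
  rd <- read_movie_tiff(dir, "b")
  expect_equal(rd$channels, bg$channels)
  expect_equal(rd$optics$pixel_size_nm, opt$pixel_size_nm)
  expect_equal(rd$seed, 21)
})
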