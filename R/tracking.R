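#' TrackMate-compatible default tracking parameters
#'
#' The detection, linking and track-filter settings used for NM2 filament
#' movies, exposed as a config block: LoG detector with estimated blob
#' diameter 1 um and quality threshold 100 (midpoint of the 50-200 range,
#' in detector units calibrated to estimated total spot counts), simple LAP
#' linking with 1 um linking max distance, 0.5 um gap-closing max distance
#' and max frame gap 2, and a track filter keeping net displacements above
#' 150 nm.
#'
#' @return Named list of parameters (nm units for distances).
#' @export
trackmate_defaults <- function() {
  list(detector = "LoG",
       estimated_diameter_nm = 1000,
       quality_threshold = 100,
       tracker = "Simple LAP",
       linking_max_nm = 1000,
       gap_closing_max_nm = 500,
       max_frame_gap = 2,
       min_displacement_nm = 150)
}

#' Subtract an averaged background stack from a movie
#'
#' Per channel, the mean frame of the background stack is subtracted from
#' every movie frame; negative pixels are clipped to zero.
#'
#' @param movie,background `"movie_stack"` objects with matching field sizes;
#'   every movie channel must be present in the background stack.
#' @return The background-subtracted `"movie_stack"`.
#' @export
subtract_background <- function(movie, background) {
  stopifnot(inherits(movie, "movie_stack"), inherits(background, "movie_stack"))
  for (ch in names(movie$channels)) {
    if (is.null(background$channels[[ch]]))
      stop("background stack lacks channel ", ch, call. = FALSE)
    bg <- background$channels[[ch]]
    if (!identical(dim(bg)[1:2], dim(movie$channels[[ch]])[1:2]))
      stop("background and movie field sizes differ", call. = FALSE)
    mbg <- apply(bg, c(1, 2), mean)
    arr <- movie$channels[[ch]]
    arr <- sweep(arr, c(1, 2), mbg)
    movie$channels[[ch]] <- pmax(arr, 0)
  }
  movie$background_subtracted <- TRUE
  movie
}

# Laplacian-of-Gaussian kernel at the blob scale, negated so spots are
# maxima, and calibrated so the response to a diffraction-limited spot of
# unit total counts is 1 (quality therefore estimates total spot counts).
log_kernel <- function(optics, estimated_diameter_nm = 1000) {
  px <- optics$pixel_size_nm
  sig <- (estimated_diameter_nm / 2) / sqrt(2) / px
  r <- ceiling(4 * sig)
  xs <- -r:r
  k <- outer(xs, xs, function(x, y) {
    rr <- x^2 + y^2
    -((rr - 2 * sig^2) / sig^4) * exp(-rr / (2 * sig^2))
  })
  k <- k - mean(k)   # zero-sum: flat background gives zero response
  spsf <- optics$psf_sigma_nm / px
  psf <- outer(xs, xs, function(x, y) exp(-(x^2 + y^2) / (2 * spsf^2)))
  psf <- psf / sum(psf)
  k / sum(k * psf)
}

# 2-D FFT of the kernel embedded (centre at [1,1], wrapped) in an ny x nx
# field, for fast circular convolution; the kernel FFT is computed once per
# movie and reused across frames.
kernel_fft <- function(k, ny, nx) {
  r <- (nrow(k) - 1) / 2
  if (2 * r + 1 > min(ny, nx))
    stop("field smaller than the detection kernel", call. = FALSE)
  pad <- matrix(0, ny, nx)
  ii <- ((-r:r) %% ny) + 1
  jj <- ((-r:r) %% nx) + 1
  pad[ii, jj] <- k
  stats::fft(pad)
}

conv_fft <- function(frame, kfft) {
  Re(stats::fft(stats::fft(frame) * kfft, inverse = TRUE)) / length(frame)
}

#' Detect fluorescent spots in one frame
#'
#' Laplacian-of-Gaussian detection at a scale matched to the estimated blob
#' diameter, as used for NM2 filament movies. Local maxima of the filtered
#' response above `quality_threshold` are kept (closely spaced maxima merged,
#' strongest wins), positions are refined to sub-pixel precision by an
#' intensity-weighted centroid, and the total intensity is integrated over
#' the spot footprint (a circle of the estimated radius).
#'
#' @param frame Numeric matrix of (background-subtracted) counts.
#' @param optics An [optics_model()] (pixel size, PSF width).
#' @param estimated_diameter_nm Estimated blob diameter (default 1000 nm).
#' @param quality_threshold Detector threshold in quality units (estimated
#'   total spot counts); default from [trackmate_defaults()].
#' @param kfft Optional precomputed kernel FFT (from the internal
#'   `kernel_fft`), reused across frames by [detect_movie()].
#' @return A `data.frame` with columns `x_nm`, `y_nm`, `total_intensity`,
#'   `mean_intensity`, `radius_nm`, `quality` (possibly 0 rows). Coordinates
#'   are pixel-centre referenced: the centre of pixel (0, 0) is at
#'   (`pixel_size/2`, `pixel_size/2`) nm.
#' @export
detect_spots <- function(frame, optics = optics_model(),
                         estimated_diameter_nm = 1000,
                         quality_threshold = trackmate_defaults()$quality_threshold,
                         kfft = NULL) {
  stopifnot(is.matrix(frame), estimated_diameter_nm > 0)
  px <- optics$pixel_size_nm
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(kfft))
    kfft <- kernel_fft(log_kernel(optics, estimated_diameter_nm), ny, nx)
  resp <- conv_fft(frame, kfft)
  # 8-neighbour local maxima above threshold (border excluded)
  ok <- resp >= quality_threshold
  ok[c(1, ny), ] <- FALSE; ok[, c(1, nx)] <- FALSE
  idx <- which(ok)
  if (!length(idx)) return(empty_spots())
  iy <- (idx - 1) %% ny + 1
  ix <- (idx - 1) %/% ny + 1
  is_max <- vapply(seq_along(idx), function(j) {
    v <- resp[iy[j], ix[j]]
    all(v >= resp[(iy[j] - 1):(iy[j] + 1), (ix[j] - 1):(ix[j] + 1)])
  }, logical(1))
  iy <- iy[is_max]; ix <- ix[is_max]
  if (!length(iy)) return(empty_spots())
  q <- resp[cbind(iy, ix)]
  # suppress maxima closer than the blob radius (strongest first)
  ord <- order(-q)
  keep <- logical(length(ord))
  min_sep_px <- (estimated_diameter_nm / 2) / px
  for (j in ord) {
    if (any(keep & ((ix - ix[j])^2 + (iy - iy[j])^2) < min_sep_px^2)) next
    keep[j] <- TRUE
  }
  iy <- iy[keep]; ix <- ix[keep]; q <- q[keep]
  radius_px <- (estimated_diameter_nm / 2) / px
  out <- lapply(seq_along(iy), function(j) {
    cy <- iy[j]; cx <- ix[j]
    w <- ceiling(radius_px)
    ys <- max(1, cy - w):min(ny, cy + w)
    xs <- max(1, cx - w):min(nx, cx + w)
    patch <- frame[ys, xs, drop = FALSE]
    dmask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius_px^2
    vals <- patch * dmask
    tot <- sum(vals)
    # intensity-weighted centroid within the footprint
    if (tot > 0) {
      cyr <- sum(row(patch) * vals) / tot + ys[1] - 1
      cxr <- sum(col(patch) * vals) / tot + xs[1] - 1
    } else { cyr <- cy; cxr <- cx }
    data.frame(x_nm = (cxr - 0.5) * px, y_nm = (cyr - 0.5) * px,
               total_intensity = tot, mean_intensity = tot / sum(dmask),
               radius_nm = estimated_diameter_nm / 2, quality = q[j])
  })
  do.call(rbind, out)
}

empty_spots <- function() {
  data.frame(x_nm = numeric(), y_nm = numeric(), total_intensity = numeric(),
             mean_intensity = numeric(), radius_nm = numeric(),
             quality = numeric())
}

#' Detect spots in every frame of a movie channel
#'
#' @param movie A (background-subtracted) `"movie_stack"`.
#' @param channel Channel label to detect in.
#' @param ... Passed to [detect_spots()].
#' @return A `data.frame` of spots with a 0-based `frame` column.
#' @export
detect_movie <- function(movie, channel = "488",
                         estimated_diameter_nm = 1000, ...) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("no channel ", channel, call. = FALSE)
  kfft <- kernel_fft(log_kernel(movie$optics, estimated_diameter_nm),
                     dim(arr)[1], dim(arr)[2])
  res <- lapply(seq_len(dim(arr)[3]), function(f) {
    s <- detect_spots(arr[, , f], movie$optics, estimated_diameter_nm,
                      kfft = kfft, ...)
    if (nrow(s)) cbind(frame = f - 1L, s) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- cbind(frame = integer(), empty_spots())
  out
}

# optimal one-to-one assignment between two point sets with a distance cap;
# returns integer vector: for each row index, the matched column or NA.
# Jaqaman-style augmented LAP: alternative (no-link) cost = cap^2.
lap_match <- function(xy1, xy2, max_dist) {
  n <- nrow(xy1); m <- nrow(xy2)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  big <- max_dist^2 * 1e6
  cost <- matrix(big, n + m, n + m)
  linkable <- d2 <= max_dist^2
  # deterministic tie-break: minuscule penalty increasing with spot indices
  eps <- outer(seq_len(n), seq_len(m), function(i, j) (i * (m + 1) + j) * 1e-9)
  cost[1:n, 1:m] <- ifelse(linkable, d2 + eps * max_dist^2, big)
  for (i in seq_len(n)) cost[i, m + i] <- max_dist^2          # no link (death)
  for (j in seq_len(m)) cost[n + j, j] <- max_dist^2          # no link (birth)
  cost[(n + 1):(n + m), (m + 1):(m + n)] <- 0                 # lower-right block
  sol <- clue::solve_LSAP(cost)
  match_to <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && linkable[i, j]) match_to[i] <- j
  }
  match_to
}

#' Link detected spots into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment minimizing total
#' squared displacement under the linking distance cap (simple LAP), followed
#' by gap closing: track ends are joined to later track starts within the
#' gap-closing distance and with at most `max_frame_gap` missing frames.
#' Assignment ties are broken toward the lowest combined spot indices for
#' reproducibility. Every spot belongs to at most one track.
#'
#' @param spots Spot table from [detect_movie()] (columns `frame`, `x_nm`,
#'   `y_nm`, intensities).
#' @param linking_max_nm Frame-to-frame linking distance cap (default 1000).
#' @param gap_closing_max_nm Gap-closing distance cap (default 500).
#' @param max_frame_gap Maximum missing frames bridged by gap closing
#'   (default 2).
#' @return The spot table with a `track_id` column, class `"track_table"`.
#' @export
link_tracks <- function(spots, linking_max_nm = 1000,
                        gap_closing_max_nm = 500, max_frame_gap = 2) {
  if (nrow(spots) == 0) {
    spots$track_id <- integer()
    class(spots) <- c("track_table", "data.frame")
    return(spots)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track_id <- NA_integer_
  frames <- sort(unique(spots$frame))
  next_id <- 1L
  idx_by_frame <- split(seq_len(nrow(spots)), spots$frame)
  prev <- idx_by_frame[[as.character(frames[1])]]
  spots$track_id[prev] <- seq_along(prev)
  next_id <- length(prev) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur <- idx_by_frame[[as.character(frames[fi])]]
    contiguous <- frames[fi] - frames[fi - 1] == 1
    if (contiguous && length(prev)) {
      m <- lap_match(cbind(spots$x_nm[prev], spots$y_nm[prev]),
                     cbind(spots$x_nm[cur], spots$y_nm[cur]), linking_max_nm)
      for (i in seq_along(prev))
        if (!is.na(m[i])) spots$track_id[cur[m[i]]] <- spots$track_id[prev[i]]
    }
    new <- cur[is.na(spots$track_id[cur])]
    if (length(new)) {
      spots$track_id[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev <- cur
  }
  # gap closing between track segment ends and starts
  repeat {
    segs <- split(seq_len(nrow(spots)), spots$track_id)
    ends <- t(vapply(segs, function(ii) {
      j <- ii[which.max(spots$frame[ii])]
      c(j, spots$frame[j], spots$x_nm[j], spots$y_nm[j])
    }, numeric(4)))
    starts <- t(vapply(segs, function(ii) {
      j <- ii[which.min(spots$frame[ii])]
      c(j, spots$frame[j], spots$x_nm[j], spots$y_nm[j])
    }, numeric(4)))
    ids <- as.integer(names(segs))
    ne <- nrow(ends)
    d2 <- outer(ends[, 3], starts[, 3], "-")^2 +
      outer(ends[, 4], starts[, 4], "-")^2
    dt <- outer(ends[, 2], starts[, 2], function(a, b) b - a)
    allowed <- dt >= 2 & (dt - 1) <= max_frame_gap &
      d2 <= gap_closing_max_nm^2
    if (!any(allowed)) break
    big <- gap_closing_max_nm^2 * 1e6
    costs <- ifelse(allowed, d2 + dt, big)   # prefer shorter gaps on ties
    # greedy-free optimal matching via LAP on the allowed pairs
    n <- ne
    cost <- matrix(big, 2 * n, 2 * n)
    cost[1:n, 1:n] <- costs
    for (i in 1:n) { cost[i, n + i] <- gap_closing_max_nm^2 + max_frame_gap + 1
                     cost[n + i, i] <- gap_closing_max_nm^2 + max_frame_gap + 1 }
    cost[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0
    sol <- clue::solve_LSAP(cost)
    merged <- FALSE
    for (i in 1:n) {
      j <- sol[i]
      if (j <= n && allowed[i, j]) {
        from <- ids[j]; to <- ids[i]
        if (from != to) {
          spots$track_id[spots$track_id == from] <- to
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  spots$track_id <- match(spots$track_id, unique(spots$track_id))
  class(spots) <- c("track_table", "data.frame")
  spots
}

#' Per-track kinematics, displacement filter and censoring annotation
#'
#' Computes per-track net displacement, duration, run length and mean
#' velocity, drops tracks with net displacement at or below the filter
#' (default 150 nm), and flags censored tracks: a track is
#' `censored_at_end = TRUE` when its final position lies within one PSF sigma
#' of an end of its actin segment, and `censored = TRUE` additionally when
#' the track is still present in the final movie frame (observation-window
#' truncation). Censored tracks are retained in the table but should be
#' excluded from run-length fitting.
#'
#' Run length is the net start-to-end displacement projected onto the track's
#' actin segment (nearest segment by mean perpendicular distance); mean
#' velocity is run length over duration.
#'
#' @param tracks A `"track_table"` from [link_tracks()].
#' @param optics An [optics_model()].
#' @param layout Optional [layout_actin()] table for segment assignment and
#'   end-censoring; without it, run length falls back to the unprojected net
#'   displacement and `censored_at_end` is `NA`.
#' @param min_displacement_nm Displacement filter (default 150).
#' @param last_frame 0-based index of the final movie frame (default: max
#'   frame present in `tracks`).
#' @return A `data.frame` of class `"track_stats"`, one row per retained
#'   track: `track_id`, `n_spots`, `first_frame`, `last_frame`,
#'   `displacement_nm`, `run_length_um`, `duration_s`, `mean_velocity_nm_s`,
#'   `mean_total_intensity`, `segment_id`, `censored_at_end`, `censored`.
#' @export
filter_and_annotate <- function(tracks, optics = optics_model(),
                                layout = NULL,
                                min_displacement_nm = trackmate_defaults()$min_displacement_nm,
                                last_frame = NULL) {
  if (nrow(tracks) == 0) return(empty_track_stats())
  if (is.null(last_frame)) last_frame <- max(tracks$frame)
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    dx <- tr$x_nm[n] - tr$x_nm[1]; dy <- tr$y_nm[n] - tr$y_nm[1]
    disp <- sqrt(dx^2 + dy^2)
    dur <- (tr$frame[n] - tr$frame[1]) * optics$frame_interval_s
    seg_id <- NA_integer_; cen_end <- NA; run_nm <- disp
    if (!is.null(layout)) {
      dmean <- vapply(seq_len(nrow(layout)), function(i) {
        s <- layout[i, ]
        mean(point_segment_dist(tr$x_nm, tr$y_nm, s))
      }, numeric(1))
      seg_id <- layout$segment_id[which.min(dmean)]
      s <- layout[layout$segment_id == seg_id, ]
      ux <- (s$x1_nm - s$x0_nm); uy <- (s$y1_nm - s$y0_nm)
      L <- sqrt(ux^2 + uy^2); ux <- ux / L; uy <- uy / L
      run_nm <- abs(dx * ux + dy * uy)
      dend <- min(sqrt((tr$x_nm[n] - s$x0_nm)^2 + (tr$y_nm[n] - s$y0_nm)^2),
                  sqrt((tr$x_nm[n] - s$x1_nm)^2 + (tr$y_nm[n] - s$y1_nm)^2))
      cen_end <- dend <= optics$psf_sigma_nm
    }
    data.frame(track_id = tr$track_id[1], n_spots = n,
               first_frame = tr$frame[1], last_frame = tr$frame[n],
               displacement_nm = disp, run_length_um = run_nm / 1000,
               duration_s = dur,
               mean_velocity_nm_s = if (dur > 0) run_nm / dur else 0,
               mean_total_intensity = mean(tr$total_intensity),
               segment_id = seg_id, censored_at_end = cen_end,
               censored = isTRUE(cen_end) | tr$frame[n] >= last_frame)
  })
  out <- do.call(rbind, rows)
  out <- out[out$displacement_nm > min_displacement_nm, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_stats", "data.frame")
  out
}

empty_track_stats <- function() {
  out <- data.frame(track_id = integer(), n_spots = integer(),
                    first_frame = integer(), last_frame = integer(),
                    displacement_nm = numeric(), run_length_um = numeric(),
                    duration_s = numeric(), mean_velocity_nm_s = numeric(),
                    mean_total_intensity = numeric(), segment_id = integer(),
                    censored_at_end = logical(), censored = logical())
  class(out) <- c("track_stats", "data.frame")
  out
}

point_segment_dist <- function(x, y, seg) {
  vx <- seg$x1_nm - seg$x0_nm; vy <- seg$y1_nm - seg$y0_nm
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((x - seg$x0_nm) * vx + (y - seg$y0_nm) * vy) / L2, 0), 1)
  sqrt((x - (seg$x0_nm + t * vx))^2 + (y - (seg$y0_nm + t * vy))^2)
}

#' Run length and mean velocity of a single track
#'
#' @param track Rows of a `"track_table"` for one track.
#' @param optics An [optics_model()].
#' @param layout Optional layout for along-actin projection.
#' @return Named numeric vector `c(run_length_um = , mean_velocity_nm_s = )`.
#' @export
track_statistics <- function(track, optics = optics_model(), layout = NULL) {
  st <- filter_and_annotate(track, optics, layout, min_displacement_nm = -1)
  if (nrow(st) != 1L) stop("expected a single track", call. = FALSE)
  if (st$duration_s <= 0) stop("track duration is zero", call. = FALSE)
  c(run_length_um = st$run_length_um,
    mean_velocity_nm_s = st$mean_velocity_nm_s)
}

#' Measure per-frame intensity in a square ROI of a second channel
#'
#' For two-color stoichiometry, the second channel is measured in a square
#' ROI (default 1 um) centred on the tracked first-channel position in every
#' frame; per-track intensities are the across-frame averages of the ROI
#' sums.
#'
#' @param movie Background-subtracted `"movie_stack"`.
#' @param tracks `"track_table"` with tracked positions (first channel).
#' @param channel Channel to measure (e.g. `"561"`).
#' @param roi_nm ROI side length in nm (default 1000).
#' @return `data.frame` with `track_id` and `roi_intensity` (mean per-frame
#'   ROI sum).
#' @export
measure_roi_intensity <- function(movie, tracks, channel = "561",
                                  roi_nm = 1000) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("no channel ", channel, call. = FALSE)
  px <- movie$optics$pixel_size_nm
  ny <- dim(arr)[1]; nx <- dim(arr)[2]
  half <- roi_nm / 2
  sums <- vapply(seq_len(nrow(tracks)), function(k) {
    cx <- tracks$x_nm[k] / px + 0.5; cy <- tracks$y_nm[k] / px + 0.5
    xs <- max(1, round(cx - half / px)):min(nx, round(cx + half / px))
    ys <- max(1, round(cy - half / px)):min(ny, round(cy + half / px))
    sum(arr[ys, xs, tracks$frame[k] + 1])
  }, numeric(1))
  agg <- tapply(sums, tracks$track_id, mean)
  data.frame(track_id = as.integer(names(agg)),
             roi_intensity = as.numeric(agg))
}

#' Track a movie end to end
#'
#' Convenience wrapper: background subtraction (when a background stack is
#' supplied), per-frame LoG detection, LAP linking with gap closing, and the
#' displacement filter with censoring annotation.
#'
#' @param movie A `"movie_stack"`.
#' @param background Optional background `"movie_stack"`.
#' @param channel Channel to track.
#' @param layout Optional [layout_actin()] table for censoring annotation.
#' @param params Tracking parameters, see [trackmate_defaults()].
#' @return List with `spots` (`"track_table"`) and `tracks`
#'   (`"track_stats"`).
#' @export
track_movie <- function(movie, background = NULL, channel = "488",
                        layout = NULL, params = trackmate_defaults()) {
  if (!is.null(background)) movie <- subtract_background(movie, background)
  spots <- detect_movie(movie, channel,
                        estimated_diameter_nm = params$estimated_diameter_nm,
                        quality_threshold = params$quality_threshold)
  linked <- link_tracks(spots, params$linking_max_nm,
                        params$gap_closing_max_nm, params$max_frame_gap)
  stats <- filter_and_annotate(linked, movie$optics, layout,
                               params$min_displacement_nm,
                               last_frame = dim(movie$channels[[channel]])[3] - 1)
  list(spots = linked, tracks = stats, movie = movie)
}
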