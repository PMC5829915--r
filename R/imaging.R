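#' Optics and camera model for synthetic TIRF movies
#'
#' Describes the imaging system used by the renderer. Defaults emulate a
#' 100x TIRF objective on an EMCCD with 13 um camera pixels (130 nm/px in the
#' sample plane) and a diffraction-limited PSF of 140 nm sigma. EM gain and
#' camera offset are folded into the photons/counts scaling.
#'
#' @param pixel_size_nm Sample-plane pixel size in nm (default 130).
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm (default 140).
#'   Must satisfy `psf_sigma_nm >= pixel_size_nm / 3` (sampling sanity).
#' @param frame_interval_s Time between frames, seconds.
#' @param photons_per_fluorophore_per_frame Expected camera counts contributed
#'   by one fluorophore per frame.
#' @param background_mean Mean background level, counts.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param frame_count Number of frames per movie.
#' @param image_shape Field size in pixels, `c(ny, nx)`.
#' @return An object of class `"optics_model"`.
#' @export
optics_model <- function(pixel_size_nm = 130, psf_sigma_nm = 140,
                         frame_interval_s = 2,
                         photons_per_fluorophore_per_frame = 80,
                         background_mean = 20, read_noise_sd = 2,
                         frame_count = 100, image_shape = c(256, 256)) {
  vals <- c(pixel_size_nm, psf_sigma_nm, frame_interval_s,
            photons_per_fluorophore_per_frame + 1e-12, background_mean,
            read_noise_sd, frame_count, image_shape)
  if (any(!is.finite(vals)) || any(vals[-c(4, 5, 6)] <= 0) ||
      background_mean < 0 || read_noise_sd < 0)
    stop("optics parameters must be positive (noise terms nonnegative)",
         call. = FALSE)
  if (psf_sigma_nm < pixel_size_nm / 3)
    stop("`psf_sigma_nm` must be at least `pixel_size_nm`/3", call. = FALSE)
  structure(
    list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
         frame_interval_s = frame_interval_s,
         photons_per_fluorophore_per_frame = photons_per_fluorophore_per_frame,
         background_mean = background_mean, read_noise_sd = read_noise_sd,
         frame_count = frame_count, image_shape = as.integer(image_shape)),
    class = "optics_model"
  )
}

#' Peak signal-to-noise ratio of a rendered spot
#'
#' SNR is defined as the expected peak pixel amplitude of a spot over the
#' noise SD at that pixel (Poisson shot noise of background plus signal, plus
#' read noise): `peak / sqrt(background + peak + read^2)`.
#'
#' @param optics An [optics_model()].
#' @param n_fluorophores Fluorophores on the spot (default 30, a full
#'   filament).
#' @return Numeric SNR.
#' @export
spot_snr <- function(optics, n_fluorophores = 30) {
  total <- n_fluorophores * optics$photons_per_fluorophore_per_frame
  sig_px <- optics$psf_sigma_nm / optics$pixel_size_nm
  peak <- total / (2 * pi * sig_px^2)
  peak / sqrt(optics$background_mean + peak + optics$read_noise_sd^2)
}

#' Lay out actin filaments in the imaging field
#'
#' Places `n_filaments` random line segments (surface-immobilized actin
#' filaments) in the field, with all endpoints inside the field and segment
#' start points separated by at least `min_start_separation_um`. Lengths are
#' drawn from a truncated normal distribution. The segment direction defines
#' the actin polarity: myosin filaments move from the start `(x0, y0)` toward
#' the end `(x1, y1)`.
#'
#' @param n_filaments Number of actin filaments (`>= 1`).
#' @param length_um_mean,length_um_sd Length distribution parameters
#'   (micrometres); `length_um_sd = 0` gives fixed lengths.
#' @param optics An [optics_model()] (for field size and pixel size).
#' @param min_start_separation_um Minimum distance between segment starts.
#' @param margin_um Border kept clear of endpoints.
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `"actin_layout"` with columns
#'   `segment_id`, `x0_nm`, `y0_nm`, `x1_nm`, `y1_nm`, `length_um`.
#' @export
layout_actin <- function(n_filaments, length_um_mean = 12, length_um_sd = 2,
                         optics = optics_model(),
                         min_start_separation_um = 2, margin_um = 0.5,
                         seed = NULL) {
  stopifnot(n_filaments >= 1, length_um_mean > 0, length_um_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  px <- optics$pixel_size_nm
  w_nm <- optics$image_shape[2] * px
  h_nm <- optics$image_shape[1] * px
  m_nm <- margin_um * 1000
  segs <- vector("list", n_filaments)
  starts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_filaments)) {
    placed <- FALSE
    for (try in 1:2000) {
      L <- if (length_um_sd > 0) {
        v <- stats::rnorm(1, length_um_mean, length_um_sd)
        if (v <= 1) next
        v
      } else length_um_mean
      x0 <- stats::runif(1, m_nm, w_nm - m_nm)
      y0 <- stats::runif(1, m_nm, h_nm - m_nm)
      th <- stats::runif(1, 0, 2 * pi)
      x1 <- x0 + 1000 * L * cos(th)
      y1 <- y0 + 1000 * L * sin(th)
      if (x1 < m_nm || x1 > w_nm - m_nm || y1 < m_nm || y1 > h_nm - m_nm) next
      if (nrow(starts) > 0 &&
          min(sqrt((starts[, 1] - x0)^2 + (starts[, 2] - y0)^2)) <
            min_start_separation_um * 1000) next
      segs[[i]] <- data.frame(segment_id = i, x0_nm = x0, y0_nm = y0,
                              x1_nm = x1, y1_nm = y1, length_um = L)
      starts <- rbind(starts, c(x0, y0))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("field too small to place ", n_filaments, " actin filaments",
           call. = FALSE)
  }
  out <- do.call(rbind, segs)
  class(out) <- c("actin_layout", "data.frame")
  out
}

# position along a segment (um from the start) -> field coordinates (nm)
segment_xy <- function(segment, pos_um) {
  f <- pmin(pos_um * 1000 / (segment$length_um * 1000), 1)
  cbind(x_nm = segment$x0_nm + f * (segment$x1_nm - segment$x0_nm),
        y_nm = segment$y0_nm + f * (segment$y1_nm - segment$y0_nm))
}

#' Simulate myosin filaments moving in an imaging field
#'
#' Couples the stochastic simulator to an actin layout: each myosin filament
#' is assigned an actin segment (cycling through the layout), lands at a
#' uniformly random position along it at a uniformly random start time, and
#' its trajectory is simulated with the segment's length as the actin track
#' length. Per-filament fluorophore counts per channel are derived from the
#' whole-filament composition (one fluorophore per molecule of the species
#' mapped to that channel, thinned by the labeling efficiency).
#'
#' @param layout An [layout_actin()] result.
#' @param n_filaments Number of myosin filaments; defaults to one per actin
#'   segment.
#' @param composition A fixed [filament_composition()] or a sampler function.
#' @param species Named list of species `A` and `B` (see [simulate_run()]).
#' @param conditions A [simulation_conditions()]; `actin_length_um` is
#'   overridden per segment.
#' @param optics An [optics_model()].
#' @param channel_of_species Map from species to emission channel label,
#'   default `c(A = "561", B = "488", tail = "561")` (TMR-labeled NM2-A and
#'   tail fragments, AF488-labeled NM2-B).
#' @param labeling_efficiency Probability that a molecule carries a working
#'   fluorophore (default 1).
#' @param start_window_s Filament attachment times are drawn uniformly from
#'   `[0, start_window_s]`; default half of the movie.
#' @param seed Master seed.
#' @return A list of class `"imaging_truth"`: `filaments` (per-filament
#'   table: composition totals, fluorophore counts per channel, start time,
#'   segment, true run statistics) and `positions` (per frame and filament:
#'   true `x_nm`, `y_nm`, `NA` when the filament is not on the actin).
#' @export
simulate_field <- function(layout, n_filaments = nrow(layout),
                           composition,
                           species = list(A = nm2_species("NM2A"),
                                          B = nm2_species("NM2B")),
                           conditions = simulation_conditions(),
                           optics = optics_model(),
                           channel_of_species = c(A = "561", B = "488",
                                                  tail = "561"),
                           labeling_efficiency = 1,
                           start_window_s = NULL, seed = 1) {
  sampler <- if (is.function(composition)) composition else function() composition
  frame_times <- (seq_len(optics$frame_count) - 1) * optics$frame_interval_s
  movie_T <- max(frame_times)
  if (is.null(start_window_s)) start_window_s <- movie_T / 2
  channels <- unique(unname(channel_of_species))
  fil_rows <- vector("list", n_filaments)
  pos_rows <- vector("list", n_filaments)
  for (i in seq_len(n_filaments)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    seg <- layout[((i - 1) %% nrow(layout)) + 1, ]
    comp <- sampler()
    t0 <- stats::runif(1, 0, start_window_s)
    cond_i <- conditions
    cond_i$actin_length_um <- seg$length_um
    cond_i$max_time_s <- min(conditions$max_time_s, movie_T - t0)
    run <- simulate_run(comp, species, cond_i, seed = NULL,
                        frame_times_s = frame_times - t0)
    tot <- comp$half + comp$distal
    nflu <- vapply(channels, function(ch) {
      mols <- sum(tot[names(channel_of_species)[channel_of_species == ch]])
      if (labeling_efficiency >= 1) mols
      else stats::rbinom(1, mols, labeling_efficiency)
    }, numeric(1))
    xy <- segment_xy(seg, run$frame_pos_um)
    present <- !is.na(run$frame_pos_um)
    fil_rows[[i]] <- data.frame(
      filament_id = i, seed = si, segment_id = seg$segment_id,
      start_time_s = t0,
      nA_mol = tot[["A"]], nB_mol = tot[["B"]], ntail_mol = tot[["tail"]],
      n_motors_half = run$n_motors,
      run_length_um = run$run_length_um, duration_s = run$duration_s,
      mean_velocity_nm_s = run$mean_velocity_nm_s,
      termination = run$termination, censored = run$censored,
      t(nflu))
    pos_rows[[i]] <- data.frame(
      filament_id = i, frame = seq_along(frame_times) - 1L,
      x_nm = ifelse(present, xy[, "x_nm"], NA_real_),
      y_nm = ifelse(present, xy[, "y_nm"], NA_real_))
  }
  filaments <- do.call(rbind, fil_rows)
  names(filaments)[match(make.names(channels), names(filaments))] <-
    paste0("n_fluor_", channels)
  # channels with no labeled molecules anywhere are not imaged
  channels <- channels[vapply(channels, function(ch)
    sum(filaments[[paste0("n_fluor_", ch)]]) > 0, logical(1))]
  structure(
    list(filaments = filaments, positions = do.call(rbind, pos_rows),
         layout = layout, optics = optics, channels = channels,
         channel_of_species = channel_of_species, seed = seed),
    class = "imaging_truth"
  )
}

# additive Gaussian spot rendering on a frame matrix (counts, in place)
add_spot <- function(frame, x_nm, y_nm, total_counts, optics) {
  px <- optics$pixel_size_nm
  sig <- optics$psf_sigma_nm / px
  cx <- x_nm / px - 0.5   # pixel-centre referenced coordinates
  cy <- y_nm / px - 0.5
  r <- ceiling(5 * sig)
  ny <- nrow(frame); nx <- ncol(frame)
  ix <- max(0, floor(cx) - r):min(nx - 1, ceiling(cx) + r)
  iy <- max(0, floor(cy) - r):min(ny - 1, ceiling(cy) + r)
  if (!length(ix) || !length(iy)) return(frame)
  gx <- exp(-((ix - cx)^2) / (2 * sig^2))
  gy <- exp(-((iy - cy)^2) / (2 * sig^2))
  patch <- (total_counts / (2 * pi * sig^2)) * outer(gy, gx)
  frame[iy + 1, ix + 1] <- frame[iy + 1, ix + 1] + patch
  frame
}

# static actin line profile (expected counts) for one channel
actin_profile <- function(layout, optics, counts_per_um = 400) {
  frame <- matrix(0, optics$image_shape[1], optics$image_shape[2])
  step_um <- optics$pixel_size_nm / 2000   # half-pixel sampling
  for (i in seq_len(nrow(layout))) {
    seg <- layout[i, ]
    s <- seq(0, seg$length_um, by = step_um)
    xy <- segment_xy(seg, s)
    for (j in seq_along(s))
      frame <- add_spot(frame, xy[j, 1], xy[j, 2],
                        counts_per_um * step_um, optics)
  }
  frame
}

#' Render a synthetic TIRF movie
#'
#' Renders each myosin filament as a 2-D Gaussian of SD `psf_sigma_nm`
#' centred at its interpolated position in every frame where it is attached,
#' with integrated counts equal to (fluorophores on the filament) x
#' (photons per fluorophore per frame). Pixel values are Poisson draws around
#' background + signal plus Gaussian read noise, rounded and clipped at zero.
#' The actin channel (if requested) is a static line profile rendered from
#' the layout with the same noise model.
#'
#' @param truth An [simulate_field()] result.
#' @param seed Integer seed for the noise.
#' @param actin_channel Label for a static actin channel, or `NULL` to omit.
#' @return A list of class `"movie_stack"`: `channels` (named list of
#'   `ny x nx x frames` arrays of counts), `optics`, `truth`, `seed`.
#' @export
render_movie <- function(truth, seed = 1, actin_channel = "640") {
  stopifnot(inherits(truth, "imaging_truth"))
  optics <- truth$optics
  set.seed(seed)
  nf <- optics$frame_count
  ny <- optics$image_shape[1]; nx <- optics$image_shape[2]
  pos <- truth$positions
  fil <- truth$filaments
  w_nm <- nx * optics$pixel_size_nm; h_nm <- ny * optics$pixel_size_nm
  clipped <- !is.na(pos$x_nm) &
    (pos$x_nm < 0 | pos$x_nm > w_nm | pos$y_nm < 0 | pos$y_nm > h_nm)
  if (any(clipped)) {
    warning("some trajectory points fall outside the field; clipped")
    truth$positions$clipped <- clipped
  }
  channels <- list()
  for (ch in truth$channels) {
    counts <- fil[[paste0("n_fluor_", ch)]] *
      optics$photons_per_fluorophore_per_frame
    arr <- array(0, c(ny, nx, nf))
    for (f in seq_len(nf)) {
      idx <- which(pos$frame == f - 1 & !is.na(pos$x_nm))
      frame <- matrix(0, ny, nx)
      for (k in idx) {
        cnt <- counts[pos$filament_id[k]]
        if (cnt > 0)
          frame <- add_spot(frame, pos$x_nm[k], pos$y_nm[k], cnt, optics)
      }
      arr[, , f] <- frame
    }
    channels[[ch]] <- arr
  }
  if (!is.null(actin_channel)) {
    prof <- actin_profile(truth$layout, optics)
    channels[[actin_channel]] <- array(prof, c(ny, nx, nf))
  }
  for (ch in names(channels)) {
    n <- length(channels[[ch]])
    noisy <- stats::rpois(n, channels[[ch]] + optics$background_mean) +
      stats::rnorm(n, 0, optics$read_noise_sd)
    channels[[ch]] <- array(pmax(0, round(noisy)), c(ny, nx, nf))
  }
  structure(list(channels = channels, optics = optics, truth = truth,
                 seed = seed),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Movie stack: %d channel(s) [%s], %d x %d px, %d frames\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  invisible(x)
}

#' Render a signal-free background stack for calibration
#'
#' Frames containing only the background and noise model (Poisson shot noise
#' around the background mean plus Gaussian read noise), mirroring the
#' calibration procedure of capturing 20 images of an empty field per channel.
#'
#' @param optics An [optics_model()].
#' @param n_frames Number of frames (default 20).
#' @param channels Channel labels to generate.
#' @param seed Integer seed.
#' @return A `"movie_stack"` without ground truth.
#' @export
render_background_stack <- function(optics = optics_model(), n_frames = 20,
                                    channels = "488", seed = 1) {
  stopifnot(n_frames >= 1)
  set.seed(seed)
  ny <- optics$image_shape[1]; nx <- optics$image_shape[2]
  chans <- list()
  for (ch in channels) {
    n <- ny * nx * n_frames
    noisy <- stats::rpois(n, optics$background_mean) +
      stats::rnorm(n, 0, optics$read_noise_sd)
    chans[[ch]] <- array(pmax(0, round(noisy)), c(ny, nx, n_frames))
  }
  structure(list(channels = chans, optics = optics, truth = NULL, seed = seed),
            class = "movie_stack")
}

#' Write / read a movie stack as multi-page TIFF with a JSON sidecar
#'
#' One 16-bit unsigned multi-page TIFF per channel
#' (`<basename>_<channel>.tif`), plus `<basename>_meta.json` holding the
#' optics parameters, seed and channel map, and (when ground truth is
#' attached) `<basename>_truth.csv` with the true per-frame positions and
#' per-filament fluorophore counts.
#'
#' @param movie A `"movie_stack"`.
#' @param dir Output directory (created if needed).
#' @param basename File name stem.
#' @return `write_movie_tiff` returns the written paths invisibly;
#'   `read_movie_tiff` returns a `"movie_stack"` (without ground truth).
#' @export
write_movie_tiff <- function(movie, dir, basename = "movie") {
  stopifnot(inherits(movie, "movie_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(f) pmin(arr[, , f], 65535) / 65535)
    p <- file.path(dir, sprintf("%s_%s.tif", basename, ch))
    tiff::writeTIFF(pages, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  meta <- list(optics = unclass(movie$optics), seed = movie$seed,
               channels = names(movie$channels))
  mp <- file.path(dir, paste0(basename, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, mp)
  if (!is.null(movie$truth)) {
    tp <- file.path(dir, paste0(basename, "_truth.csv"))
    write_csv_commented(
      merge(movie$truth$positions, movie$truth$filaments, by = "filament_id"),
      tp, comments = c(paste("master_seed:", movie$truth$seed)))
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(dir, basename = "movie") {
  mp <- file.path(dir, paste0(basename, "_meta.json"))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  o <- meta$optics
  optics <- optics_model(o$pixel_size_nm, o$psf_sigma_nm, o$frame_interval_s,
                         o$photons_per_fluorophore_per_frame,
                         o$background_mean, o$read_noise_sd, o$frame_count,
                         o$image_shape)
  chans <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", basename, ch)),
                            all = TRUE)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * 65535)
    chans[[ch]] <- arr
  }
  structure(list(channels = chans, optics = optics, truth = NULL,
                 seed = meta$seed),
            class = "movie_stack")
}
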