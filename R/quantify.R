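#' Reference intensity calibration from single-species filaments
#'
#' The stoichiometric estimators are anchored on the average total
#' fluorescence intensity of filaments of known composition: 100% NM2-B
#' filaments give `I_2B_ref` (in the 488 channel) and 100% NM2-A filaments
#' give `I_2A_ref` (561 channel). Intensities are averaged per track first
#' and then across tracks, unweighted by track duration.
#'
#' @param tracks_pure Named list of `"track_stats"` tables (or numeric
#'   vectors of per-track mean intensities), one per reference channel, e.g.
#'   `list("488" = <pure NM2-B tracks>, "561" = <pure NM2-A tracks>)`.
#' @param min_tracks Minimum tracks per condition (default 10).
#' @return Object of class `"intensity_calibration"`: per channel the
#'   reference mean, SE and n.
#' @export
calibrate_reference <- function(tracks_pure, min_tracks = 10) {
  if (!length(tracks_pure)) stop("empty reference input", call. = FALSE)
  refs <- lapply(tracks_pure, function(tr) {
    v <- if (is.numeric(tr)) tr else tr$mean_total_intensity
    if (length(v) < min_tracks)
      stop("need at least ", min_tracks, " reference tracks", call. = FALSE)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  if (any(vapply(refs, function(r) r[["mean"]] <= 0, logical(1))))
    stop("reference intensities must be positive", call. = FALSE)
  structure(list(refs = refs), class = "intensity_calibration")
}

#' @export
print.intensity_calibration <- function(x, ...) {
  cat("Intensity calibration:\n")
  for (ch in names(x$refs))
    cat(sprintf("  channel %s: I_ref = %.1f +/- %.1f (n = %d tracks)\n",
                ch, x$refs[[ch]][["mean"]], x$refs[[ch]][["se"]],
                as.integer(x$refs[[ch]][["n"]])))
  invisible(x)
}

ref_of <- function(calibration, channel) {
  r <- calibration$refs[[channel]]
  if (is.null(r)) stop("no calibration for channel ", channel, call. = FALSE)
  r
}

#' Motor number of a co-filament from its fluorescence intensity
#'
#' The motor-bearing fraction of a co-filament relative to a 100% NM2-B
#' filament is `R = I_cof / I_2B_ref`, and the average number of motor
#' domains per co-filament is `n = R * n_c` with `n_c = 60` motors per
#' filament. Standard errors are propagated from the intensity SE and the
#' calibration SE.
#'
#' @param I_cof Mean total intensity of the co-filaments (same channel as the
#'   reference); a vector is averaged with an SE.
#' @param calibration An [calibrate_reference()] result.
#' @param channel Reference channel (default `"488"`).
#' @param n_c Motors per 100% filament (default 60).
#' @return Object of class `"composition_estimate"` with `R`, `R_se`,
#'   `n_motors`, `n_motors_se`.
#' @export
estimate_motor_number <- function(I_cof, calibration, channel = "488",
                                  n_c = 60) {
  ref <- ref_of(calibration, channel)
  if (any(I_cof < 0)) stop("intensities must be >= 0", call. = FALSE)
  m <- mean(I_cof)
  se_m <- if (length(I_cof) > 1) stats::sd(I_cof) / sqrt(length(I_cof)) else 0
  R <- m / ref[["mean"]]
  R_se <- R * sqrt((if (m > 0) (se_m / m)^2 else 0) +
                     (ref[["se"]] / ref[["mean"]])^2)
  structure(list(R = R, R_se = R_se, n_motors = R * n_c,
                 n_motors_se = R_se * n_c, n_c = n_c,
                 I_cof = m, n_filaments = length(I_cof)),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  if (!is.null(x$R))
    cat(sprintf("Motor-bearing fraction R = %.3f +/- %.3f -> n = %.1f +/- %.1f motors per filament\n",
                x$R, x$R_se, x$n_motors, x$n_motors_se))
  if (!is.null(x$F_2A))
    cat(sprintf("NM2-A fraction F_2A = %.3f +/- %.3f\n", x$F_2A, x$F_2A_se))
  invisible(x)
}

#' NM2-A fraction of mixed-paralog filaments from two-color intensities
#'
#' With reference intensities of 100% NM2-A and 100% NM2-B filaments, the
#' fraction of NM2-A molecules in a mixed filament is
#' \deqn{F_{2A} = \frac{I_{2A}/I_{2A,ref}}{I_{2A}/I_{2A,ref} + I_{2B}/I_{2B,ref}}.}
#' The estimator is invariant to rescaling both mixed intensities by the same
#' factor.
#'
#' @param I_2A_mix,I_2B_mix Mean intensities of the mixed filaments in the
#'   NM2-A and NM2-B channels (vectors are averaged; equal lengths give
#'   per-filament normalized fractions averaged with an SE).
#' @param calibration An [calibrate_reference()] result holding both
#'   channels.
#' @param channel_A,channel_B Channel labels (defaults `"561"`, `"488"`).
#' @return `"composition_estimate"` with `F_2A` and `F_2A_se`.
#' @export
estimate_fraction_2A <- function(I_2A_mix, I_2B_mix, calibration,
                                 channel_A = "561", channel_B = "488") {
  if (any(I_2A_mix < 0) || any(I_2B_mix < 0))
    stop("intensities must be >= 0", call. = FALSE)
  refA <- ref_of(calibration, channel_A)
  refB <- ref_of(calibration, channel_B)
  a <- I_2A_mix / refA[["mean"]]
  b <- I_2B_mix / refB[["mean"]]
  if (all(a + b == 0))
    stop("undefined composition: both normalized intensities are zero",
         call. = FALSE)
  f <- a / (a + b)
  se <- if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else 0
  structure(list(F_2A = mean(f), F_2A_se = se, per_filament = f,
                 n_filaments = length(f)),
            class = "composition_estimate")
}

freedman_diaconis_bins <- function(x, first_edge) {
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(range(x)) / max(1, ceiling(sqrt(length(x))))
  if (bw <= 0) bw <- max(abs(x), 1) / 10
  edges <- seq(first_edge, max(x) + bw, by = bw)
  if (length(edges) < 4) edges <- seq(first_edge, max(x) + bw, length.out = 5)
  edges
}

#' Fit a single-exponential run-length distribution
#'
#' Censored runs (filaments that reached the actin end or were cut off by
#' the observation window) are excluded by default, mirroring the analysis
#' rule for motility data; the fitted characteristic length is then a
#' minimum estimate of the true run length. Two methods:
#'
#' * `"histogram_lsq"` (default): least-squares fit of `A * exp(-x / lambda)`
#'   to a frequency histogram with Freedman-Diaconis bins whose first edge is
#'   at the detection minimum (the 150 nm displacement filter).
#' * `"mle"`: maximum likelihood for a shifted exponential,
#'   `lambda = mean(x - detection_minimum)`, `SE = lambda / sqrt(n)`.
#'
#' An optional censoring-aware mode (`include_censored = TRUE`, MLE only)
#' treats censored values as right-censored observations:
#' `lambda = sum(x - detection_minimum) / n_uncensored`.
#'
#' @param run_lengths_um Run lengths in micrometres.
#' @param censored Logical vector marking censored runs (default none).
#' @param method `"histogram_lsq"` or `"mle"`.
#' @param detection_minimum_um Lower detection bound (default 0.15, the
#'   150 nm displacement filter).
#' @param min_n Minimum number of uncensored values required (default 30).
#' @param include_censored Use the censoring-aware MLE instead of excluding
#'   censored runs.
#' @return Object of class `"runlength_fit"`: `lambda_um`, `se_um`,
#'   `n_tracks`, `method`, `r_squared` (histogram method), `hist` data.
#' @export
fit_run_length <- function(run_lengths_um, censored = NULL,
                           method = c("histogram_lsq", "mle"),
                           detection_minimum_um = 0.15, min_n = 30,
                           include_censored = FALSE) {
  method <- match.arg(method)
  if (is.null(censored)) censored <- rep(FALSE, length(run_lengths_um))
  stopifnot(length(censored) == length(run_lengths_um))
  if (any(run_lengths_um < 0)) stop("run lengths must be nonnegative",
                                    call. = FALSE)
  keep <- run_lengths_um >= detection_minimum_um
  x_all <- run_lengths_um[keep]
  cen <- censored[keep]
  x <- x_all[!cen]
  if (length(x) < min_n)
    stop("need at least ", min_n, " uncensored run lengths", call. = FALSE)
  if (include_censored) {
    lambda <- sum(x_all - detection_minimum_um) / length(x)
    se <- lambda / sqrt(length(x))
    return(structure(list(lambda_um = lambda, se_um = se,
                          n_tracks = length(x_all), method = "mle_censored",
                          r_squared = NA_real_, hist = NULL),
                     class = "runlength_fit"))
  }
  lambda_mle <- mean(x - detection_minimum_um)
  if (method == "mle") {
    return(structure(list(lambda_um = lambda_mle,
                          se_um = lambda_mle / sqrt(length(x)),
                          n_tracks = length(x), method = "mle",
                          r_squared = NA_real_, hist = NULL),
                     class = "runlength_fit"))
  }
  edges <- freedman_diaconis_bins(x, detection_minimum_um)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  A0 <- length(x) * diff(edges)[1] / lambda_mle *
    exp(detection_minimum_um / lambda_mle)
  fit <- minpack.lm::nlsLM(count ~ A * exp(-mid / lambda), data = df,
                           start = list(A = A0, lambda = lambda_mle),
                           lower = c(1e-12, 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((df$count - mean(df$count))^2)
  structure(list(lambda_um = co["lambda", "Estimate"],
                 se_um = co["lambda", "Std. Error"],
                 n_tracks = length(x), method = "histogram_lsq",
                 r_squared = r2, hist = df, fit = fit),
            class = "runlength_fit")
}

#' @export
print.runlength_fit <- function(x, ...) {
  cat(sprintf("Single-exponential run-length fit (%s): lambda = %.3f +/- %.3f um (n = %d%s)\n",
              x$method, x$lambda_um, x$se_um, x$n_tracks,
              if (!is.na(x$r_squared)) sprintf(", R^2 = %.3f", x$r_squared)
              else ""))
  invisible(x)
}

#' Fit a Gaussian to a velocity distribution
#'
#' Least-squares Gaussian fit to a Freedman-Diaconis frequency histogram,
#' returning `mu` and `sigma`; the arithmetic mean is always reported, and is
#' the recommended summary when the distribution is visibly non-Gaussian
#' (mixed-paralog filaments), flagged when the Gaussian fit's R-squared falls
#' below `gaussian_r2_min`.
#'
#' @param velocities_nm_s Per-track mean velocities (nm/s), at least 30.
#' @param gaussian_r2_min R-squared below which the single-Gaussian fit is
#'   flagged poor (default 0.8).
#' @param min_n Minimum sample size (default 30).
#' @return Object of class `"velocity_fit"`: `mu`, `mu_se`, `sigma`,
#'   `arithmetic_mean`, `arithmetic_se`, `sd`, `r_squared`, `gaussian_ok`,
#'   `n_tracks`.
#' @export
fit_velocity <- function(velocities_nm_s, gaussian_r2_min = 0.8, min_n = 30) {
  v <- velocities_nm_s
  if (length(v) < min_n)
    stop("need at least ", min_n, " velocities", call. = FALSE)
  am <- mean(v); s <- stats::sd(v)
  if (s == 0) {
    return(structure(list(mu = am, mu_se = 0, sigma = 0, arithmetic_mean = am,
                          arithmetic_se = 0, sd = 0, r_squared = 1,
                          gaussian_ok = TRUE, n_tracks = length(v)),
                     class = "velocity_fit"))
  }
  edges <- freedman_diaconis_bins(v, min(v) - 1e-9)
  h <- graphics::hist(v, breaks = edges, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  A0 <- max(h$counts)
  fit <- try(minpack.lm::nlsLM(
    count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)), data = df,
    start = list(A = A0, mu = am, sigma = s),
    lower = c(1e-12, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    mu <- am; mu_se <- s / sqrt(length(v)); sigma <- s; r2 <- NA_real_
  } else {
    co <- summary(fit)$coefficients
    mu <- co["mu", "Estimate"]; mu_se <- co["mu", "Std. Error"]
    sigma <- abs(co["sigma", "Estimate"])
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((df$count - mean(df$count))^2)
  }
  structure(list(mu = mu, mu_se = mu_se, sigma = sigma,
                 arithmetic_mean = am,
                 arithmetic_se = s / sqrt(length(v)), sd = s,
                 r_squared = r2,
                 gaussian_ok = !is.na(r2) && r2 >= gaussian_r2_min,
                 n_tracks = length(v)),
            class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("Velocity: Gaussian mu = %.1f +/- %.1f nm/s (sigma = %.1f, R^2 = %.2f%s); arithmetic mean = %.1f +/- %.1f nm/s (n = %d)\n",
              x$mu, x$mu_se, x$sigma, x$r_squared,
              if (x$gaussian_ok) "" else ", poor fit",
              x$arithmetic_mean, x$arithmetic_se, x$n_tracks))
  invisible(x)
}

#' Run length versus motor number regression with x-intercept
#'
#' Weighted least-squares line through (motors per half filament,
#' characteristic run length) points; the x-axis intercept
#' `-intercept/slope` estimates the minimum motor number required to sustain
#' processive movement. Its SE is computed by first-order error propagation
#' from the parameter covariance, with a parametric bootstrap alternative.
#'
#' @param n_motors_half Motor counts per half filament.
#' @param lambda_um Characteristic run lengths (micrometres).
#' @param lambda_se_um Optional SEs for weighting (`1/se^2`); equal weights
#'   when omitted.
#' @param n_boot Bootstrap replicates for the alternative SE (0 disables).
#' @param seed Seed for the bootstrap.
#' @return Object of class `"motor_regression"`: `slope`, `intercept`,
#'   `x_intercept`, `x_intercept_se` (delta method),
#'   `x_intercept_se_boot`, and the `lm` fit.
#' @export
regress_runlength_vs_motors <- function(n_motors_half, lambda_um,
                                        lambda_se_um = NULL, n_boot = 1000,
                                        seed = 1) {
  if (length(unique(n_motors_half)) < 2)
    stop("need at least 2 distinct motor numbers", call. = FALSE)
  stopifnot(length(n_motors_half) == length(lambda_um))
  w <- if (is.null(lambda_se_um)) rep(1, length(lambda_um))
       else 1 / lambda_se_um^2
  df <- data.frame(n = n_motors_half, lambda = lambda_um, w = w)
  fit <- stats::lm(lambda ~ n, data = df, weights = w)
  b <- stats::coef(fit)
  if (abs(b[["n"]]) < 1e-12)
    stop("slope is zero: x-intercept undefined", call. = FALSE)
  x0 <- -b[["(Intercept)"]] / b[["n"]]
  V <- stats::vcov(fit)
  g <- c(-1 / b[["n"]], b[["(Intercept)"]] / b[["n"]]^2)
  x0_se <- sqrt(drop(t(g) %*% V %*% g))
  x0_boot <- NA_real_
  if (n_boot > 0 && !is.null(lambda_se_um)) {
    set.seed(seed)
    bs <- replicate(n_boot, {
      lb <- stats::rnorm(length(lambda_um), lambda_um, lambda_se_um)
      fb <- stats::lm(lb ~ n_motors_half, weights = w)
      cb <- stats::coef(fb)
      if (abs(cb[2]) < 1e-12) NA_real_ else -cb[1] / cb[2]
    })
    x0_boot <- stats::sd(bs, na.rm = TRUE)
  }
  structure(list(slope = b[["n"]], intercept = b[["(Intercept)"]],
                 x_intercept = x0, x_intercept_se = x0_se,
                 x_intercept_se_boot = x0_boot, fit = fit),
            class = "motor_regression")
}

#' @export
print.motor_regression <- function(x, ...) {
  cat(sprintf("Run length vs motor number: slope = %.4f um/motor, intercept = %.3f um\n",
              x$slope, x$intercept))
  cat(sprintf("  x-intercept = %.2f +/- %.2f motors per half filament\n",
              x$x_intercept, x$x_intercept_se))
  invisible(x)
}

#' Build a kymograph along an actin segment
#'
#' Position-time image: for each frame, the intensity profile along the
#' segment (sampled at pixel-size steps, bilinear interpolation) is reduced
#' across a perpendicular line width by the maximum (or mean). Diagonal
#' streaks indicate processive movement; vertical lines indicate stalled or
#' end-accumulated filaments.
#'
#' @param movie A `"movie_stack"`.
#' @param segment One row of an [layout_actin()] table.
#' @param channel Channel label.
#' @param line_width_px Perpendicular width in pixels (default 3).
#' @param stat `"max"` or `"mean"` across the width.
#' @return Matrix of class `"kymograph"` (rows = frames, columns = position
#'   along the segment) with attributes `position_um` and `time_s`.
#' @export
build_kymograph <- function(movie, segment, channel = "488",
                            line_width_px = 3, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("no channel ", channel, call. = FALSE)
  px <- movie$optics$pixel_size_nm
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nf <- dim(arr)[3]
  s_um <- seq(0, segment$length_um, by = px / 1000)
  xy <- segment_xy(segment, s_um)
  if (any(xy[, 1] < 0 | xy[, 1] > nx * px | xy[, 2] < 0 | xy[, 2] > ny * px))
    stop("segment extends outside the field", call. = FALSE)
  ux <- segment$x1_nm - segment$x0_nm; uy <- segment$y1_nm - segment$y0_nm
  L <- sqrt(ux^2 + uy^2)
  pxn <- -uy / L; pyn <- ux / L   # unit normal
  offs <- (seq_len(line_width_px) - (line_width_px + 1) / 2) * px
  bilinear <- function(frame, x_px, y_px) {
    x0 <- pmax(1, pmin(nx - 1, floor(x_px))); y0 <- pmax(1, pmin(ny - 1, floor(y_px)))
    fx <- pmax(0, pmin(1, x_px - x0)); fy <- pmax(0, pmin(1, y_px - y0))
    frame[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      frame[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      frame[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      frame[cbind(y0 + 1, x0 + 1)] * fx * fy
  }
  kymo <- matrix(0, nf, length(s_um))
  for (f in seq_len(nf)) {
    frame <- arr[, , f]
    prof <- matrix(0, length(offs), length(s_um))
    for (o in seq_along(offs)) {
      xs <- (xy[, 1] + offs[o] * pxn) / px + 0.5
      ys <- (xy[, 2] + offs[o] * pyn) / px + 0.5
      prof[o, ] <- bilinear(frame, xs, ys)
    }
    kymo[f, ] <- if (stat == "max") apply(prof, 2, max) else colMeans(prof)
  }
  attr(kymo, "position_um") <- s_um
  attr(kymo, "time_s") <- (seq_len(nf) - 1) * movie$optics$frame_interval_s
  class(kymo) <- c("kymograph", "matrix", "array")
  kymo
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(attr(x, "position_um"), attr(x, "time_s"), t(unclass(x)),
                  xlab = "position along actin (um)", ylab = "time (s)",
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}
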