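test_that("reference calibration averages per track, not per frame", {
  cal <- calibrate_reference(list("488" = rep(1000, 12)))
  expect_equal(cal$refs[["488"]][["mean"]], 1000)
  expect_equal(cal$refs[["488"]][["se"]], 0)

  # two tracks of very different durations weigh equally
  cal <- calibrate_reference(list("488" = c(1000, 2000)), min_tracks = 2)
  expect_equal(cal$refs[["488"]][["mean"]], 1500)

  expect_error(calibrate_reference(list("488" = rep(1, 3))), "at least")
  expect_error(calibrate_reference(list()), "empty")
})

test_that("motor-number estimation is the calibrated intensity ratio times n_c", {
  cal <- calibrate_reference(list("488" = rep(1000, 12)))
  est <- estimate_motor_number(1000, cal)
  expect_equal(est$R, 1)
  expect_equal(est$n_motors, 60)
  est <- estimate_motor_number(500, cal)
  expect_equal(est$n_motors, 30)
  # linearity in I_cof
  ns <- vapply(c(100, 200, 400, 800),
               function(I) estimate_motor_number(I, cal)$n_motors, numeric(1))
  expect_equal(ns / ns[1], c(1, 2, 4, 8))
  expect_error(estimate_motor_number(100, cal, channel = "561"),
               "no calibration")
})

test_that("two-color paralog fraction is normalized, bounded and scale invariant", {
  cal <- calibrate_reference(list("488" = rep(100, 12),
                                  "561" = rep(100, 12)))
  expect_equal(estimate_fraction_2A(50, 50, cal)$F_2A, 0.5)
  expect_equal(estimate_fraction_2A(0, 70, cal)$F_2A, 0)
  expect_equal(estimate_fraction_2A(70, 0, cal)$F_2A, 1)
  expect_equal(estimate_fraction_2A(30, 70, cal)$F_2A, 0.3)

  # scale invariance and complement identity
  set.seed(5)
  for (i in 1:10) {
    a <- stats::runif(1, 1, 100); b <- stats::runif(1, 1, 100)
    k <- stats::runif(1, 0.1, 10)
    f1 <- estimate_fraction_2A(a, b, cal)$F_2A
    f2 <- estimate_fraction_2A(k * a, k * b, cal)$F_2A
    expect_equal(f1, f2)
    expect_equal(f1 + estimate_fraction_2A(b, a, cal)$F_2A, 1)
  }
  expect_error(estimate_fraction_2A(0, 0, cal), "undefined")
})

test_that("run-length fitting recovers a known exponential under truncation", {
  # exponential MLE with no truncation equals the sample mean
  x <- rep(2.5, 40)
  f <- fit_run_length(x, method = "mle", detection_minimum_um = 0)
  expect_equal(f$lambda_um, 2.5)

  # 1463 truncated draws from Exp(1.95 um): shifted MLE recovers lambda
  set.seed(19)
  draws <- stats::rexp(6000, 1 / 1.95)
  draws <- draws[draws >= 0.15][1:1463]
  f <- fit_run_length(draws, method = "mle")
  expect_lt(abs(f$lambda_um - 1.95), 3 * f$se_um)

  # histogram least squares agrees with MLE within 5% on a large sample
  set.seed(23)
  big <- stats::rexp(12000, 1 / 1.95)
  big <- big[big >= 0.15][1:10000]
  fm <- fit_run_length(big, method = "mle")
  fh <- fit_run_length(big, method = "histogram_lsq")
  expect_lt(abs(fh$lambda_um - fm$lambda_um) / fm$lambda_um, 0.05)
  expect_gt(fh$r_squared, 0.95)

  # censoring-aware MLE uses censored values in the numerator only
  xs <- c(1, 2, 3, rep(1.5, 30))
  cen <- c(TRUE, TRUE, FALSE, rep(FALSE, 30))
  fc <- fit_run_length(xs, cen, include_censored = TRUE,
                       detection_minimum_um = 0)
  expect_equal(fc$lambda_um, sum(xs) / 31)

  expect_error(fit_run_length(rep(1, 10)), "at least")
  expect_error(fit_run_length(c(-1, rep(1, 40))), "nonnegative")
})

test_that("excluding end-censored runs reduces the run-length bias", {
  # runs ending at the actin end carry only a lower bound on their length;
  # treating them as complete observations inflates lambda
  set.seed(31)
  true_lambda <- 2
  L <- 4
  full <- stats::rexp(4000, 1 / true_lambda)
  censored <- full > L
  obs <- pmin(full, L)
  keep <- obs >= 0.15
  f_excl <- fit_run_length(obs[keep], censored[keep], method = "mle")
  f_incl <- fit_run_length(obs[keep], method = "mle")   # censoring ignored
  bias_excl <- abs(f_excl$lambda_um - true_lambda)
  # exclusion gives an underestimate ("minimum estimate"), inclusion-as-exact
  # is also biased; the survival-analysis mode beats both
  f_surv <- fit_run_length(obs[keep], censored[keep], include_censored = TRUE)
  expect_lt(abs(f_surv$lambda_um - true_lambda), bias_excl)
  expect_lt(f_excl$lambda_um, true_lambda)
})

test_that("velocity fitting returns Gaussian parameters and flags non-Gaussian mixtures", {
  f <- fit_velocity(rep(43, 50))
  expect_equal(f$mu, 43)
  expect_equal(f$sigma, 0)
  expect_equal(f$arithmetic_mean, 43)

  set.seed(37)
  v <- stats::rnorm(1463, 43, 21)
  f <- fit_velocity(v)
  expect_lt(abs(f$mu - 43), 3 * max(f$mu_se, 21 / sqrt(1463)))
  expect_true(f$gaussian_ok)
  expect_equal(f$sigma, 21, tolerance = 0.15)

  # bimodal paralog mixture: single Gaussian flagged poor, arithmetic mean
  # remains the reported summary
  set.seed(41)
  vm <- c(stats::rnorm(700, 43, 10), stats::rnorm(700, 133, 10))
  fm <- fit_velocity(vm)
  expect_false(fm$gaussian_ok)
  expect_equal(fm$arithmetic_mean, mean(vm))

  expect_error(fit_velocity(rep(43, 5)), "at least")
})

test_that("motor-number regression reproduces two-point algebra and recovers a known line", {
  # exact line through the origin
  r <- regress_runlength_vs_motors(c(5, 10), c(0.5, 1.0))
  expect_equal(r$x_intercept, 0, tolerance = 1e-9)

  # two-point algebra on the co-filament run lengths
  r <- regress_runlength_vs_motors(c(9, 18), c(0.45, 0.98))
  expect_equal(r$slope, (0.98 - 0.45) / 9, tolerance = 1e-9)
  expect_equal(r$x_intercept, 9 - 0.45 / r$slope, tolerance = 1e-6)
  expect_equal(r$x_intercept, 1.36, tolerance = 0.01)

  # recovery study: three points from a known line plus noise
  set.seed(43)
  slope <- 0.06; x0_true <- 4
  ns <- c(9, 14, 18)
  lam_true <- slope * (ns - x0_true)
  se <- c(0.04, 0.05, 0.03)
  x0s <- replicate(300, {
    lam <- stats::rnorm(3, lam_true, se)
    regress_runlength_vs_motors(ns, lam, se, n_boot = 0)$x_intercept
  })
  expect_lt(abs(mean(x0s) - x0_true), 2 * stats::sd(x0s) / sqrt(length(x0s)) + 0.15)

  # delta-method SE is on the same scale as the replicate scatter
  r <- regress_runlength_vs_motors(ns, lam_true + c(0.01, -0.02, 0.01), se)
  expect_gt(r$x_intercept_se, 0)
  expect_true(is.finite(r$x_intercept_se_boot))

  expect_error(regress_runlength_vs_motors(c(9, 9), c(1, 1.2)), "distinct")
  expect_error(regress_runlength_vs_motors(c(5, 10), c(1, 1)), "slope")
})

test_that("kymographs show vertical lines for static spots and slopes matching velocity", {
  opt <- optics_model(frame_interval_s = 2, frame_count = 40,
                      image_shape = c(96, 96),
                      photons_per_fluorophore_per_frame = 500)
  seg <- data.frame(segment_id = 1L, x0_nm = 1500, y0_nm = 6000,
                    x1_nm = 11500, y1_nm = 6000, length_um = 10)
  px <- opt$pixel_size_nm

  frame_for <- function(x_nm) {
    f <- matrix(0, 96, 96)
    nm2motility:::add_spot(f, x_nm, 6000, 30 * 500, opt)
  }
  mk_movie <- function(xs) {
    arr <- array(0, c(96, 96, length(xs)))
    for (f in seq_along(xs)) arr[, , f] <- frame_for(xs[f])
    structure(list(channels = list("488" = arr), optics = opt, truth = NULL,
                   seed = 1), class = "movie_stack")
  }

  # static spot: column of the maximum is constant over time
  ky <- build_kymograph(mk_movie(rep(5000, 10)), seg)
  peaks <- apply(unclass(ky), 1, which.max)
  expect_lt(stats::sd(attr(ky, "position_um")[peaks]), 0.05)

  # constant velocity 80 nm/s: kymograph slope recovers it within 5%
  v <- 80
  times <- (0:39) * opt$frame_interval_s
  ky <- build_kymograph(mk_movie(2000 + v * times), seg)
  pos_um <- attr(ky, "position_um")[apply(unclass(ky), 1, which.max)]
  fit <- stats::lm(pos_um ~ times)
  expect_equal(unname(stats::coef(fit)[2]) * 1000, v, tolerance = 0.05)

  # empty movie: uniform background, no structure
  arr <- array(5, c(96, 96, 4))
  mv <- structure(list(channels = list("488" = arr), optics = opt,
                       truth = NULL, seed = 1), class = "movie_stack")
  ky <- build_kymograph(mv, seg)
  expect_true(all(abs(ky - 5) < 1e-9))

  off <- seg; off$x1_nm <- 2e5
  expect_error(build_kymograph(mv, off), "outside")
})
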