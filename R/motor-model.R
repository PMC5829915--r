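#' Define a myosin motor species
#'
#' A motor species bundles the single-motor kinetic and mechanical parameters
#' used throughout the simulator: the duty ratio (fraction of the ATPase cycle
#' spent strongly bound to actin), the cycle time, the working-stroke step size
#' and the unloaded gliding speed. Headless tail fragments are represented by
#' `duty_ratio = 0`; they co-polymerize into filaments but contribute no motor
#' domains.
#'
#' The four mechanochemical numbers are linked by the consistency relation
#' `unloaded_speed = step_size / (duty_ratio * cycle_time)` for a
#' detachment-limited motor; [nm2_species()] constructs the shipped defaults
#' that way. `motor_species()` itself does not enforce the relation, so
#' hypothetical parameter sets can be explored.
#'
#' @param name Species label, e.g. `"NM2B"`.
#' @param duty_ratio Single-motor duty ratio `r`, in `[0, 1]`.
#' @param cycle_time ATPase cycle duration in seconds (`> 0`).
#' @param step_size Working stroke in nanometres (`> 0`).
#' @param unloaded_speed Unloaded gliding speed in nm/s (`>= 0`).
#' @param speed_sd Between-filament SD of the gliding speed in nm/s, used by
#'   the stochastic simulator to emulate the Gaussian velocity scatter seen in
#'   motility data; `0` disables scatter.
#' @return An object of class `"motor_species"`.
#' @seealso [species_rates()], [nm2_species()]
#' @export
motor_species <- function(name, duty_ratio, cycle_time, step_size = 8,
                          unloaded_speed = step_size / (duty_ratio * cycle_time),
                          speed_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(duty_ratio) || length(duty_ratio) != 1L ||
      is.na(duty_ratio) || duty_ratio < 0 || duty_ratio > 1)
    stop("`duty_ratio` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(cycle_time) || length(cycle_time) != 1L || cycle_time <= 0)
    stop("`cycle_time` must be a single positive number (seconds)", call. = FALSE)
  if (step_size <= 0) stop("`step_size` must be positive (nm)", call. = FALSE)
  if (duty_ratio == 0) unloaded_speed <- 0
  if (is.na(unloaded_speed) || unloaded_speed < 0)
    stop("`unloaded_speed` must be >= 0 (nm/s)", call. = FALSE)
  if (speed_sd < 0) stop("`speed_sd` must be >= 0 (nm/s)", call. = FALSE)
  structure(
    list(name = name, duty_ratio = duty_ratio, cycle_time = cycle_time,
         step_size = step_size, unloaded_speed = unloaded_speed,
         speed_sd = speed_sd),
    class = "motor_species"
  )
}

#' @export
print.motor_species <- function(x, ...) {
  cat(sprintf("Motor species \"%s\"\n", x$name))
  cat(sprintf("  duty ratio r      : %.3f\n", x$duty_ratio))
  cat(sprintf("  cycle time        : %.4g s\n", x$cycle_time))
  cat(sprintf("  step size         : %.3g nm\n", x$step_size))
  cat(sprintf("  unloaded speed    : %.3g nm/s (SD %.3g)\n",
              x$unloaded_speed, x$speed_sd))
  if (x$duty_ratio > 0 && x$duty_ratio < 1) {
    k <- species_rates(x)
    cat(sprintf("  k_att / k_det     : %.4g / %.4g s^-1\n", k[["k_att"]], k[["k_det"]]))
  }
  invisible(x)
}

#' Shipped NM2 species parameter sets
#'
#' Default parameterizations of the two nonmuscle myosin 2 paralogs studied in
#' single-filament motility assays, plus the headless NM2-B tail fragment used
#' to dilute motor number in co-filaments:
#'
#' * `NM2B`: duty ratio 0.23, unloaded speed 43 nm/s (speed SD 21 nm/s).
#' * `NM2A`: duty ratio 0.05, unloaded speed 133 nm/s (speed SD 75 nm/s).
#' * `NM2B_tail`: duty ratio 0, no motor domains, no movement.
#'
#' Cycle times are not directly measured in the motility assay; they are chosen
#' so that `unloaded_speed = step_size / (duty_ratio * cycle_time)` with an
#' 8 nm step reproduces the stated speeds. All values are plain list entries
#' and can be overridden.
#'
#' @param name One of `"NM2A"`, `"NM2B"`, `"NM2B_tail"`; `nm2_default_species()`
#'   returns all three as a named list.
#' @return A `"motor_species"` object (or a named list of them).
#' @export
nm2_species <- function(name = c("NM2B", "NM2A", "NM2B_tail")) {
  name <- match.arg(name)
  switch(name,
    NM2B = motor_species("NM2B", duty_ratio = 0.23,
                         cycle_time = 8 / (0.23 * 43), step_size = 8,
                         unloaded_speed = 43, speed_sd = 21),
    NM2A = motor_species("NM2A", duty_ratio = 0.05,
                         cycle_time = 8 / (0.05 * 133), step_size = 8,
                         unloaded_speed = 133, speed_sd = 75),
    NM2B_tail = motor_species("NM2B_tail", duty_ratio = 0,
                              cycle_time = 1, step_size = 8,
                              unloaded_speed = 0, speed_sd = 0)
  )
}

#' @rdname nm2_species
#' @export
nm2_default_species <- function() {
  list(NM2B = nm2_species("NM2B"), NM2A = nm2_species("NM2A"),
       NM2B_tail = nm2_species("NM2B_tail"))
}

#' Ensemble (filament) duty ratio of n independent motors
#'
#' The apparent duty ratio of a filament carrying `n` motor domains, i.e. the
#' probability that at least one motor is strongly bound to actin at any
#' instant, assuming motors act independently:
#' \deqn{r_f = 1 - (1 - r)^n.}
#' It is nondecreasing in both `r` and `n`, equals 0 at `n = 0` and tends to 1
#' as `n` grows for any positive duty ratio.
#'
#' @param r Single-motor duty ratio, in `[0, 1]`. May be vectorized.
#' @param n Number of motor domains, a nonnegative integer (vectorized).
#' @return The filament duty ratio, in `[0, 1]`.
#' @examples
#' filament_duty_ratio(0.67, 2)   # double-headed myosin 5a: ~0.89
#' filament_duty_ratio(0.23, 9)   # ~0.905: nine NM2-B motors suffice for 0.9
#' @export
filament_duty_ratio <- function(r, n) {
  if (!is.numeric(r) || any(is.na(r)) || any(r < 0 | r > 1))
    stop("`r` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0) ||
      any(abs(n - round(n)) > 1e-8))
    stop("`n` must be a nonnegative integer", call. = FALSE)
  1 - (1 - r)^round(n)
}

#' Minimum motor number for a target ensemble duty ratio
#'
#' Smallest integer `n` such that `filament_duty_ratio(r, n) >= target_rf`.
#' With the processivity assumption that a filament needs an ensemble duty
#' ratio of at least 0.9, a duty ratio of 0.23 (NM2-B) gives 9 motors and
#' 0.05 (NM2-A) gives 45.
#'
#' @param r Single-motor duty ratio, in `(0, 1]`.
#' @param target_rf Required filament duty ratio, in `(0, 1)`. Default 0.9.
#' @return A positive integer.
#' @examples
#' min_motors_for_processivity(0.23, 0.9)  # 9
#' min_motors_for_processivity(0.05, 0.9)  # 45
#' @export
min_motors_for_processivity <- function(r, target_rf = 0.9) {
  stopifnot(length(r) == 1L, length(target_rf) == 1L)
  if (!is.numeric(target_rf) || is.na(target_rf) ||
      target_rf <= 0 || target_rf >= 1)
    stop("`target_rf` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(r) || is.na(r) || r < 0 || r > 1)
    stop("`r` must be in [0, 1]", call. = FALSE)
  if (r == 0)
    stop("target filament duty ratio is unreachable with r = 0", call. = FALSE)
  if (r == 1) return(1L)
  # closed form, then verify against the defining inequality to absorb
  # floating-point edge cases
  n <- max(1, ceiling(log1p(-target_rf) / log1p(-r)))
  while (filament_duty_ratio(r, n) < target_rf) n <- n + 1
  while (n > 1 && filament_duty_ratio(r, n - 1) >= target_rf) n <- n - 1
  as.integer(n)
}

#' Expected motor-bearing fraction under unbiased co-polymerization
#'
#' When full-length myosin and headless tail fragments (or two paralogs) are
#' mixed at a molar ratio and polymerize randomly into filaments, the expected
#' fraction of motor-bearing molecules per filament is simply the mixing
#' proportion `a / (a + b)`. Mixing ratios 1:1, 1:2 and 1:5 give expected
#' fractions 0.50, 0.33 and 0.17.
#'
#' @param parts_fulllength Ratio parts of the full-length (motor-bearing)
#'   species, `> 0`.
#' @param parts_tail Ratio parts of the tail (headless) species, `>= 0`.
#' @return Expected full-length fraction in `(0, 1]`.
#' @export
expected_fulllength_fraction <- function(parts_fulllength, parts_tail) {
  if (!is.numeric(parts_fulllength) || !is.numeric(parts_tail) ||
      any(parts_fulllength < 0) || any(parts_tail < 0))
    stop("ratio parts must be nonnegative numbers", call. = FALSE)
  if (any(parts_fulllength + parts_tail == 0))
    stop("at least one ratio part must be positive", call. = FALSE)
  if (any(parts_fulllength <= 0))
    stop("`parts_fulllength` must be positive", call. = FALSE)
  parts_fulllength / (parts_fulllength + parts_tail)
}

#' Two-state attachment/detachment rates of a motor species
#'
#' Parameterizes the duty-ratio definition as first-order two-state kinetics:
#' a motor detaches at `k_det = 1 / (r * t_cycle)` and (re)attaches at
#' `k_att = 1 / ((1 - r) * t_cycle)`, so that the stationary bound probability
#' `(1/k_det) / (1/k_det + 1/k_att)` equals the duty ratio `r` and the full
#' cycle takes `t_cycle` seconds on average.
#'
#' @param species A [motor_species()] object with `0 < duty_ratio < 1`.
#' @return Named numeric vector `c(k_att = , k_det = )` in 1/s.
#' @export
species_rates <- function(species) {
  stopifnot(inherits(species, "motor_species"))
  r <- species$duty_ratio
  if (r <= 0 || r >= 1)
    stop("degenerate kinetics: `duty_ratio` must be strictly inside (0, 1)",
         call. = FALSE)
  c(k_att = 1 / ((1 - r) * species$cycle_time),
    k_det = 1 / (r * species$cycle_time))
}
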