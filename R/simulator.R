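#' Filament composition (molecules per half filament)
#'
#' A bipolar NM2 filament contains `molecules_per_filament` myosin molecules
#' (default 30, i.e. 60 motor domains, matching EM-derived counts), half at
#' each end. Only one half engages the actin filament at a time; its
#' composition determines the available motor domains:
#' `n = heads_per_molecule * (n_motor_molecules_A + n_motor_molecules_B)`.
#' Headless tail molecules contribute no motors.
#'
#' @param n_motor_molecules_A,n_motor_molecules_B Motor-bearing molecules of
#'   each species on the engaged half filament.
#' @param n_tail_molecules Headless tail molecules on the engaged half.
#' @param heads_per_molecule Motor domains per molecule (default 2).
#' @param distal Optional named counts for the non-engaged half (defaults to a
#'   copy of the engaged half); used only for whole-filament fluorophore
#'   counts when rendering.
#' @return An object of class `"filament_composition"`.
#' @export
filament_composition <- function(n_motor_molecules_A = 0,
                                 n_motor_molecules_B = 0,
                                 n_tail_molecules = 0,
                                 heads_per_molecule = 2,
                                 distal = NULL) {
  counts <- c(A = n_motor_molecules_A, B = n_motor_molecules_B,
              tail = n_tail_molecules)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("molecule counts must be nonnegative integers", call. = FALSE)
  if (heads_per_molecule < 1)
    stop("`heads_per_molecule` must be >= 1", call. = FALSE)
  if (is.null(distal)) distal <- counts
  structure(
    list(half = counts, distal = distal,
         heads_per_molecule = heads_per_molecule),
    class = "filament_composition"
  )
}

#' @export
print.filament_composition <- function(x, ...) {
  cat("Filament composition (engaged half):",
      sprintf("A=%d B=%d tail=%d molecules, %d motor domains\n",
              x$half[["A"]], x$half[["B"]], x$half[["tail"]], n_motors(x)))
  invisible(x)
}

#' Motor domains available on the engaged half filament
#' @param composition A [filament_composition()].
#' @return Integer count of motor domains.
#' @export
n_motors <- function(composition) {
  as.integer(composition$heads_per_molecule *
               (composition$half[["A"]] + composition$half[["B"]]))
}

#' Sample a random filament composition
#'
#' Each of the `molecules_per_filament / 2` molecules on each half filament is
#' assigned a species by an independent draw with probability proportional to
#' the mixing-ratio parts (binomial composition), emulating unbiased
#' co-polymerization of two molecular species.
#'
#' @param ratio Length-2 nonnegative numeric vector of mixing parts for the
#'   two species named in `species_pair`, e.g. `c(1, 5)` for a 1:5
#'   full-length:tail mix.
#' @param species_pair Character vector of length 2 naming the species of the
#'   two ratio parts; each must be one of `"A"`, `"B"`, `"tail"`.
#' @param molecules_per_filament Even positive molecule count (default 30).
#' @param heads_per_molecule Motor domains per molecule (default 2).
#' @param seed Optional integer seed for reproducibility.
#' @return A [filament_composition()] whose engaged and distal halves are
#'   independently sampled.
#' @export
sample_composition <- function(ratio, species_pair = c("B", "tail"),
                               molecules_per_filament = 30,
                               heads_per_molecule = 2, seed = NULL) {
  if (length(ratio) != 2L || any(ratio < 0))
    stop("`ratio` must be two nonnegative parts", call. = FALSE)
  if (sum(ratio) == 0) stop("at least one ratio part must be positive",
                            call. = FALSE)
  if (molecules_per_filament <= 0 || molecules_per_filament %% 2 != 0)
    stop("`molecules_per_filament` must be even and positive", call. = FALSE)
  species_pair <- match.arg(species_pair, c("A", "B", "tail"),
                            several.ok = TRUE)
  if (length(unique(species_pair)) != 2L)
    stop("`species_pair` must name two distinct species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- molecules_per_filament / 2
  p1 <- ratio[1] / sum(ratio)
  draw_half <- function() {
    k1 <- stats::rbinom(1, m, p1)
    counts <- c(A = 0, B = 0, tail = 0)
    counts[species_pair[1]] <- k1
    counts[species_pair[2]] <- m - k1
    counts
  }
  h <- draw_half()
  d <- draw_half()
  filament_composition(h[["A"]], h[["B"]], h[["tail"]],
                       heads_per_molecule = heads_per_molecule, distal = d)
}

#' Assay conditions for the stochastic simulator
#'
#' @param viscosity_mPas Solution viscosity in mPa·s; 1 for aqueous buffer,
#'   ~25 for 0.5% methylcellulose.
#' @param actin_length_um Length of the actin filament track, micrometres.
#' @param max_time_s Observation window, seconds.
#' @param rescue_tau0_s Rescue-window length at unit viscosity, seconds. When
#'   all motors detach, the filament lingers near the actin for
#'   `rescue_tau0_s * viscosity_mPas` seconds before diffusing away; a
#'   reattachment within the window continues the run. This collapses the
#'   diffusion physics into a single free parameter; the default (0.01 s) makes
#'   NM2-A ensembles non-processive in aqueous buffer yet robustly processive
#'   at 25-fold viscosity.
#' @return An object of class `"simulation_conditions"`.
#' @export
simulation_conditions <- function(viscosity_mPas = 1,
                                  actin_length_um = 15,
                                  max_time_s = 500,
                                  rescue_tau0_s = 0.01) {
  if (viscosity_mPas <= 0) stop("`viscosity_mPas` must be > 0", call. = FALSE)
  if (actin_length_um <= 0) stop("`actin_length_um` must be > 0", call. = FALSE)
  if (max_time_s <= 0) stop("`max_time_s` must be > 0", call. = FALSE)
  if (rescue_tau0_s < 0) stop("`rescue_tau0_s` must be >= 0", call. = FALSE)
  structure(
    list(viscosity_mPas = viscosity_mPas, actin_length_um = actin_length_um,
         max_time_s = max_time_s, rescue_tau0_s = rescue_tau0_s),
    class = "simulation_conditions"
  )
}

# deterministic counter-based seed stream: sub-seed i of a master seed
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(index)) %% 2147483629 + 1)
}

# per-filament gliding speed: Gaussian scatter truncated at a small positive
# floor so a filament never moves backwards or exactly stalls
draw_speed <- function(species) {
  if (species$duty_ratio == 0) return(0)
  if (species$speed_sd == 0) return(species$unloaded_speed)
  v <- stats::rnorm(1, species$unloaded_speed, species$speed_sd)
  while (v <= 1) v <- stats::rnorm(1, species$unloaded_speed, species$speed_sd)
  v
}

#' Simulate one processive run of a myosin filament
#'
#' Exact stochastic (Gillespie) simulation of the motor ensemble on the
#' engaged half filament. Motors of each species attach at
#' `(n_free * k_att)` and detach at `(n_bound * k_det)`; between events the
#' filament advances at the unloaded speed of the slowest currently-bound
#' species, so single-species filaments move at their species speed
#' independent of motor number, and paralog mixtures are dominated by the
#' slower species. When the bound count reaches zero, a rescue window of
#' length `rescue_tau0_s * viscosity` runs; termination causes are
#' `all_detached` (uncensored), `reached_end` and `timeout` (both censored).
#'
#' @param composition A [filament_composition()].
#' @param species Named list with elements `A` and `B` ([motor_species()]);
#'   the species whose molecules are counted by the composition. Defaults to
#'   NM2-A and NM2-B.
#' @param conditions A [simulation_conditions()].
#' @param seed Integer seed (required for reproducibility).
#' @param start_pos_um Initial position along the actin filament; `NULL`
#'   (default) draws it uniformly along the track.
#' @param frame_times_s Optional times (s, relative to run start) at which to
#'   report interpolated positions (used by the movie renderer).
#' @param record If `TRUE`, return the full event series.
#' @param speeds_nm_s Optional named vector `c(A=, B=)` of per-filament
#'   gliding speeds; by default drawn from each species' Gaussian speed
#'   scatter.
#' @return A list of class `"filament_run"` with elements `run_length_um`,
#'   `duration_s`, `mean_velocity_nm_s`, `termination`, `censored`,
#'   `bound_time` (motor-seconds), `pause_time_s`, `start_pos_um`,
#'   `final_pos_um`, `frame_pos_um`, and `events` (if recorded).
#' @export
simulate_run <- function(composition,
                         species = list(A = nm2_species("NM2A"),
                                        B = nm2_species("NM2B")),
                         conditions = simulation_conditions(),
                         seed = NULL, start_pos_um = NULL,
                         frame_times_s = numeric(), record = FALSE,
                         speeds_nm_s = NULL) {
  stopifnot(inherits(composition, "filament_composition"),
            inherits(conditions, "simulation_conditions"))
  if (!is.null(seed)) set.seed(seed)
  nA <- composition$heads_per_molecule * composition$half[["A"]]
  nB <- composition$heads_per_molecule * composition$half[["B"]]
  rate_or_zero <- function(sp) {
    if (sp$duty_ratio <= 0) c(k_att = 0, k_det = 0) else species_rates(sp)
  }
  kA <- rate_or_zero(species$A)
  kB <- rate_or_zero(species$B)
  if (nA > 0 && kA[["k_att"]] <= 0)
    stop("species A contributes motors but has degenerate rates", call. = FALSE)
  if (nB > 0 && kB[["k_att"]] <= 0)
    stop("species B contributes motors but has degenerate rates", call. = FALSE)
  if (is.null(speeds_nm_s))
    speeds_nm_s <- c(A = draw_speed(species$A), B = draw_speed(species$B))
  if (is.null(start_pos_um))
    start_pos_um <- stats::runif(1, 0, conditions$actin_length_um)
  res <- cpp_simulate_run(
    nA, nB,
    kA[["k_att"]], kA[["k_det"]], kB[["k_att"]], kB[["k_det"]],
    speeds_nm_s[["A"]] / 1000, speeds_nm_s[["B"]] / 1000,
    start_pos_um, conditions$actin_length_um,
    conditions$max_time_s,
    conditions$rescue_tau0_s * conditions$viscosity_mPas,
    as.numeric(frame_times_s), record
  )
  term <- c("all_detached", "reached_end", "timeout")[res$termination + 1L]
  structure(
    list(run_length_um = res$run_length, duration_s = res$duration,
         mean_velocity_nm_s = if (res$duration > 0)
           1000 * res$run_length / res$duration else 0,
         termination = term, censored = res$censored,
         bound_time = res$bound_time, pause_time_s = res$pause_time,
         n_events = res$n_events,
         start_pos_um = res$start_pos, final_pos_um = res$final_pos,
         speeds_nm_s = speeds_nm_s, n_motors = nA + nB,
         frame_pos_um = res$frame_pos, events = res$events,
         composition = composition),
    class = "filament_run"
  )
}

#' @export
print.filament_run <- function(x, ...) {
  cat(sprintf("Filament run: %.3f um in %.2f s (%.1f nm/s), %s%s\n",
              x$run_length_um, x$duration_s, x$mean_velocity_nm_s,
              x$termination, if (x$censored) " [censored]" else ""))
  invisible(x)
}

#' Simulate an ensemble of filament runs
#'
#' Runs `n_runs` independent simulations with per-run seeds derived
#' deterministically from the master seed (counter-based stream), so any
#' single run can be replayed bit-for-bit from its recorded seed.
#'
#' @param n_runs Number of runs (`>= 1`).
#' @param composition Either a fixed [filament_composition()] or a function
#'   `function()` returning one per run (a composition sampler).
#' @param species Named list of species `A` and `B`, as in [simulate_run()].
#' @param conditions A [simulation_conditions()].
#' @param seed Master seed (integer).
#' @return A `data.frame` of class `"run_table"` with one row per run:
#'   molecule counts, motor number, `run_length_um`, `duration_s`,
#'   `mean_velocity_nm_s`, `termination`, `censored`, `bound_time`,
#'   `pause_time_s`, `start_pos_um`, per-species drawn speeds and the per-run
#'   seed. Conditions, species and the master seed are attached as
#'   attributes.
#' @export
simulate_ensemble <- function(n_runs, composition,
                              species = list(A = nm2_species("NM2A"),
                                             B = nm2_species("NM2B")),
                              conditions = simulation_conditions(),
                              seed = 1) {
  stopifnot(n_runs >= 1)
  sampler <- if (is.function(composition)) composition else function() composition
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    comp <- sampler()
    run <- simulate_run(comp, species, conditions, seed = NULL)
    rows[[i]] <- data.frame(
      run_id = i, seed = si,
      nA_mol_half = comp$half[["A"]], nB_mol_half = comp$half[["B"]],
      ntail_mol_half = comp$half[["tail"]],
      nA_mol_filament = comp$half[["A"]] + comp$distal[["A"]],
      nB_mol_filament = comp$half[["B"]] + comp$distal[["B"]],
      ntail_mol_filament = comp$half[["tail"]] + comp$distal[["tail"]],
      n_motors_half = run$n_motors,
      run_length_um = run$run_length_um, duration_s = run$duration_s,
      mean_velocity_nm_s = run$mean_velocity_nm_s,
      termination = run$termination, censored = run$censored,
      bound_time = run$bound_time, pause_time_s = run$pause_time_s,
      start_pos_um = run$start_pos_um,
      vA_nm_s = run$speeds_nm_s[["A"]], vB_nm_s = run$speeds_nm_s[["B"]]
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "conditions") <- conditions
  attr(out, "species") <- species
  attr(out, "master_seed") <- seed
  attr(out, "sampler") <- sampler
  class(out) <- c("run_table", "data.frame")
  out
}

#' @export
print.run_table <- function(x, ...) {
  cat(sprintf("Run table: %d simulated runs (%d uncensored)\n",
              nrow(x), sum(!x$censored)))
  cat(sprintf("  mean run length (uncensored): %.3f um\n",
              mean(x$run_length_um[!x$censored])))
  cat(sprintf("  mean velocity (uncensored)  : %.1f nm/s\n",
              mean(x$mean_velocity_nm_s[!x$censored])))
  cols <- intersect(c("run_id", "n_motors_half", "run_length_um",
                      "duration_s", "mean_velocity_nm_s", "termination"),
                    names(x))
  print(utils::head(as.data.frame(x)[, cols], 5))
  if (nrow(x) > 5) cat("  ... (", nrow(x) - 5, " more runs)\n", sep = "")
  invisible(x)
}

#' Replay a single run from a run table
#'
#' Re-simulates run `run_id` of a [simulate_ensemble()] result bit-for-bit
#' from its recorded seed (the composition sampler and the run consume the
#' same RNG stream as in the original call), optionally with frame-time
#' sampling or full event recording.
#'
#' @param run_table A `"run_table"`.
#' @param run_id Row id of the run to replay.
#' @param frame_times_s,record,start_pos_um Passed to [simulate_run()].
#' @return A `"filament_run"`.
#' @export
replay_run <- function(run_table, run_id, frame_times_s = numeric(),
                       record = FALSE, start_pos_um = NULL) {
  row <- run_table[run_table$run_id == run_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("run_id not found", call. = FALSE)
  sampler <- attr(run_table, "sampler")
  set.seed(row$seed)
  comp <- sampler()
  simulate_run(comp, attr(run_table, "species"), attr(run_table, "conditions"),
               seed = NULL, start_pos_um = start_pos_um,
               frame_times_s = frame_times_s, record = record)
}
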