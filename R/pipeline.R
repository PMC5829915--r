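# ---- run configuration (YAML), validation, hashing ----------------------

num_in <- function(lo, hi) function(v) is.numeric(v) && length(v) == 1 &&
  is.finite(v) && v >= lo && v <= hi
pos_num <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0
nonneg_num <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 0
pos_int <- function(v) is.numeric(v) && length(v) == 1 && v >= 1 && v == round(v)
chr1 <- function(v) is.character(v) && length(v) == 1

species_schema <- list(
  name = chr1, duty_ratio = num_in(0, 1), cycle_time_s = pos_num,
  step_size_nm = pos_num, unloaded_speed_nm_s = nonneg_num,
  speed_sd_nm_s = nonneg_num
)

config_schema <- list(
  schema_version = pos_int,
  seed = pos_int,
  species = list(A = species_schema, B = species_schema),
  composition = list(
    molecules_per_filament = pos_int, heads_per_molecule = pos_int,
    mix_ratio = function(v) is.numeric(v) && length(v) == 2 && all(v >= 0) &&
      sum(v) > 0,
    species_pair = function(v) is.character(v) && length(v) == 2 &&
      all(v %in% c("A", "B", "tail"))
  ),
  conditions = list(viscosity_mPas = pos_num, actin_length_um = pos_num,
                    max_time_s = pos_num, rescue_tau0_s = nonneg_num),
  simulation = list(n_runs = pos_int),
  imaging = list(n_filaments_per_movie = pos_int, n_movies = pos_int,
                 length_um_mean = pos_num, length_um_sd = nonneg_num,
                 start_window_s = nonneg_num),
  optics = list(pixel_size_nm = pos_num, psf_sigma_nm = pos_num,
                frame_interval_s = pos_num,
                photons_per_fluorophore_per_frame = nonneg_num,
                background_mean = nonneg_num, read_noise_sd = nonneg_num,
                frame_count = pos_int,
                image_shape = function(v) is.numeric(v) && length(v) == 2 &&
                  all(v >= 16)),
  tracking = list(estimated_diameter_nm = pos_num, quality_threshold = pos_num,
                  linking_max_nm = pos_num, gap_closing_max_nm = pos_num,
                  max_frame_gap = function(v) pos_int(v) || v == 0,
                  min_displacement_nm = nonneg_num),
  quantification = list(
    run_length_method = function(v) chr1(v) &&
      v %in% c("histogram_lsq", "mle"),
    detection_minimum_um = nonneg_num)
)

#' Default pipeline configuration
#'
#' The shipped default [run_pipeline()] configuration: 100% NM2-B filaments
#' in aqueous buffer at smoke-test scale. All numeric keys carry their units
#' in the key name. A YAML copy ships at
#' `system.file("extdata", "default-config.yaml", package = "nm2motility")`.
#'
#' @return Nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  sp <- function(s) list(name = s$name, duty_ratio = s$duty_ratio,
                         cycle_time_s = s$cycle_time,
                         step_size_nm = s$step_size,
                         unloaded_speed_nm_s = s$unloaded_speed,
                         speed_sd_nm_s = s$speed_sd)
  cfg <- list(
    schema_version = 1,
    seed = 1,
    species = list(A = sp(nm2_species("NM2A")), B = sp(nm2_species("NM2B"))),
    composition = list(molecules_per_filament = 30, heads_per_molecule = 2,
                       mix_ratio = c(1, 0), species_pair = c("B", "tail")),
    conditions = list(viscosity_mPas = 1, actin_length_um = 15,
                      max_time_s = 500, rescue_tau0_s = 0.01),
    simulation = list(n_runs = 200),
    imaging = list(n_filaments_per_movie = 15, n_movies = 1,
                   length_um_mean = 12, length_um_sd = 2,
                   start_window_s = 60),
    optics = list(pixel_size_nm = 130, psf_sigma_nm = 140,
                  frame_interval_s = 2,
                  photons_per_fluorophore_per_frame = 80,
                  background_mean = 20, read_noise_sd = 2,
                  frame_count = 100, image_shape = c(256, 256)),
    tracking = trackmate_defaults()[c("estimated_diameter_nm",
                                      "quality_threshold", "linking_max_nm",
                                      "gap_closing_max_nm", "max_frame_gap",
                                      "min_displacement_nm")],
    quantification = list(run_length_method = "histogram_lsq",
                          detection_minimum_um = 0.15)
  )
  class(cfg) <- "run_config"
  cfg
}

validate_block <- function(x, schema, path) {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown config key: ", paste0(path, unknown[1]), call. = FALSE)
  for (key in names(schema)) {
    v <- x[[key]]
    if (is.null(v)) next  # defaults fill missing keys beforehand
    if (is.list(schema[[key]])) {
      if (!is.list(v))
        stop("config key ", path, key, " must be a block", call. = FALSE)
      validate_block(v, schema[[key]], paste0(path, key, "."))
    } else if (!schema[[key]](v)) {
      stop("invalid value for config key ", path, key, call. = FALSE)
    }
  }
  invisible(TRUE)
}

merge_defaults <- function(x, def) {
  for (key in names(def)) {
    if (is.null(x[[key]])) x[[key]] <- def[[key]]
    else if (is.list(def[[key]]) && is.list(x[[key]]))
      x[[key]] <- merge_defaults(x[[key]], def[[key]])
  }
  x
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills missing keys from
#' [default_run_config()], validates every value against the schema (unknown
#' keys are rejected, errors name the offending key) and returns the
#' validated config. Loading is deterministic given the file content.
#'
#' @param path Path to a YAML config file.
#' @return A validated `"run_config"` list.
#' @seealso [save_run_config()], [config_hash()]
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname load_run_config
#' @param config A config list to validate (missing keys filled from the
#'   defaults).
#' @export
validate_run_config <- function(config) {
  config <- lapply(config, identity)  # drop class for merging
  # validate the user-provided keys against the schema before filling
  validate_block(config, config_schema, "")
  cfg <- merge_defaults(config, unclass(default_run_config()))
  validate_block(cfg, config_schema, "")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_run_config
#' @param file Destination YAML path.
#' @export
save_run_config <- function(config, file) {
  yaml::write_yaml(canonical_config(config), file)
  invisible(file)
}

canonical_config <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x)) lapply(x[order(names(x))], sort_rec) else x
  }
  sort_rec(unclass(config))
}

#' Stable hash of a pipeline configuration
#'
#' MD5 of the canonical (recursively key-sorted) YAML serialization, so the
#' hash is recomputable from a saved config file regardless of key order.
#'
#' @param config A `"run_config"`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(canonical_config(config), tmp)
  unname(tools::md5sum(tmp))
}

config_species <- function(config) {
  mk <- function(s) motor_species(s$name, s$duty_ratio, s$cycle_time_s,
                                  s$step_size_nm, s$unloaded_speed_nm_s,
                                  s$speed_sd_nm_s)
  list(A = mk(config$species$A), B = mk(config$species$B))
}

config_conditions <- function(config) {
  with(config$conditions,
       simulation_conditions(viscosity_mPas, actin_length_um, max_time_s,
                             rescue_tau0_s))
}

config_sampler <- function(config) {
  cc <- config$composition
  function() sample_composition(cc$mix_ratio, cc$species_pair,
                                cc$molecules_per_filament,
                                cc$heads_per_molecule)
}

config_optics <- function(config) {
  o <- config$optics
  optics_model(o$pixel_size_nm, o$psf_sigma_nm, o$frame_interval_s,
               o$photons_per_fluorophore_per_frame, o$background_mean,
               o$read_noise_sd, o$frame_count, o$image_shape)
}

# ---- pipeline ------------------------------------------------------------

#' Run the simulation-to-quantification pipeline
#'
#' Executes the requested stages in order, writing all intermediates under
#' `outdir`:
#'
#' * `simulate`: [simulate_ensemble()] -> `runs.csv`.
#' * `render`: actin layout + [simulate_field()] + [render_movie()] ->
#'   per-movie TIFF channels, metadata JSON, ground-truth CSV, a shared
#'   background stack and `layout_<i>.csv`.
#' * `track`: [track_movie()] on every rendered movie -> `tracks.csv`.
#' * `quantify`: [fit_run_length()] and [fit_velocity()] on uncensored
#'   tracks -> `results.json`.
#'
#' Later stages require the earlier stages' outputs (from this call or a
#' previous one in the same `outdir`). Everything is reproducible from
#' (config, seed); every CSV carries the master seed in a header comment.
#'
#' @param config A `"run_config"` (see [load_run_config()]).
#' @param stages Subset of `c("simulate", "render", "track", "quantify")`.
#' @param outdir Output directory.
#' @return A `"result_bundle"` list: config hash, stage outputs and file
#'   paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "render", "track", "quantify"),
                         outdir = tempfile("nm2run")) {
  stages <- match.arg(stages, several.ok = TRUE)
  config <- validate_run_config(unclass(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  hash <- config_hash(config)
  seed <- config$seed
  species <- config_species(config)
  conditions <- config_conditions(config)
  sampler <- config_sampler(config)
  optics <- config_optics(config)
  bundle <- list(config_hash = hash, seed = seed, outdir = outdir,
                 paths = list(), timestamps = list(start = t_start))
  prov <- c(paste("config_hash:", hash), paste("master_seed:", seed))

  if ("simulate" %in% stages) {
    log_info("stage simulate: %d runs (seed %d, hash %s)",
             config$simulation$n_runs, seed, hash)
    runs <- simulate_ensemble(config$simulation$n_runs, sampler, species,
                              conditions, seed = seed)
    p <- file.path(outdir, "runs.csv")
    write_csv_commented(as.data.frame(runs), p, prov)
    bundle$paths$runs <- p
    bundle$runs <- runs
  }

  if ("render" %in% stages) {
    nmov <- config$imaging$n_movies
    log_info("stage render: %d movie(s)", nmov)
    bg <- render_background_stack(optics, 20, channels = c("488", "561"),
                                  seed = derive_seed(seed, 90001))
    write_movie_tiff(bg, outdir, "background")
    bundle$paths$background <- file.path(outdir, "background_488.tif")
    bundle$movies <- list()
    for (mv in seq_len(nmov)) {
      lay <- layout_actin(config$imaging$n_filaments_per_movie,
                          config$imaging$length_um_mean,
                          config$imaging$length_um_sd, optics,
                          seed = derive_seed(seed, 80000 + mv))
      truth <- simulate_field(lay, composition = sampler, species = species,
                              conditions = conditions, optics = optics,
                              start_window_s = config$imaging$start_window_s,
                              seed = derive_seed(seed, 70000 + mv))
      movie <- render_movie(truth, seed = derive_seed(seed, 60000 + mv),
                            actin_channel = NULL)
      base <- sprintf("movie_%03d", mv)
      write_movie_tiff(movie, outdir, base)
      write_csv_commented(as.data.frame(lay),
                          file.path(outdir, sprintf("layout_%03d.csv", mv)),
                          prov)
      bundle$movies[[mv]] <- list(basename = base, layout = lay,
                                  truth = truth)
    }
  }

  if ("track" %in% stages) {
    if (is.null(bundle$movies)) {
      metas <- sort(list.files(outdir, "^movie_[0-9]+_meta\\.json$"))
      if (!length(metas))
        stop("track stage requires render outputs", call. = FALSE)
      bundle$movies <- lapply(seq_along(metas), function(mv) {
        lay <- read_csv_commented(file.path(outdir,
                                            sprintf("layout_%03d.csv", mv)))
        class(lay) <- c("actin_layout", "data.frame")
        list(basename = sprintf("movie_%03d", mv), layout = lay)
      })
    }
    log_info("stage track")
    bg <- read_movie_tiff(outdir, "background")
    all_tracks <- list()
    for (mv in seq_along(bundle$movies)) {
      m <- bundle$movies[[mv]]
      movie <- read_movie_tiff(outdir, m$basename)
      tk <- track_movie(movie, bg, channel = "488", layout = m$layout,
                        params = config$tracking)
      if (nrow(tk$tracks)) {
        tk$tracks$movie <- mv
        all_tracks[[length(all_tracks) + 1]] <- tk$tracks
      }
    }
    tracks <- if (length(all_tracks)) do.call(rbind, all_tracks)
              else empty_track_stats()
    p <- file.path(outdir, "tracks.csv")
    write_csv_commented(as.data.frame(tracks), p, prov)
    bundle$paths$tracks <- p
    bundle$tracks <- tracks
  }

  if ("quantify" %in% stages) {
    if (is.null(bundle$tracks)) {
      p <- file.path(outdir, "tracks.csv")
      if (!file.exists(p))
        stop("quantify stage requires track outputs", call. = FALSE)
      bundle$tracks <- read_csv_commented(p)
    }
    log_info("stage quantify: %d tracks", nrow(bundle$tracks))
    tr <- bundle$tracks
    keep <- !tr$censored
    rl <- try(fit_run_length(tr$run_length_um[keep],
                             method = config$quantification$run_length_method,
                             detection_minimum_um =
                               config$quantification$detection_minimum_um),
              silent = TRUE)
    vf <- try(fit_velocity(tr$mean_velocity_nm_s[keep]), silent = TRUE)
    results <- list(
      config_hash = hash, seed = seed, n_tracks = nrow(tr),
      n_uncensored = sum(keep),
      run_length = if (inherits(rl, "runlength_fit"))
        list(lambda_um = rl$lambda_um, se_um = rl$se_um,
             n = rl$n_tracks, method = rl$method) else NULL,
      velocity = if (inherits(vf, "velocity_fit"))
        list(mu_nm_s = vf$mu, arithmetic_mean_nm_s = vf$arithmetic_mean,
             sd_nm_s = vf$sd, n = vf$n_tracks) else NULL)
    p <- file.path(outdir, "results.json")
    jsonlite::write_json(results, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    bundle$paths$results <- p
    bundle$results <- results
  }

  bundle$timestamps$end <- Sys.time()
  log_info("pipeline done in %.1f s",
           as.numeric(difftime(bundle$timestamps$end, t_start, units = "secs")))
  class(bundle) <- "result_bundle"
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Pipeline result bundle\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  outputs in :", x$outdir, "\n")
  if (!is.null(x$results$run_length))
    cat(sprintf("  run length : %.3f +/- %.3f um (n = %d)\n",
                x$results$run_length$lambda_um, x$results$run_length$se_um,
                x$results$run_length$n))
  if (!is.null(x$results$velocity))
    cat(sprintf("  velocity   : %.1f nm/s (arithmetic mean, n = %d)\n",
                x$results$velocity$arithmetic_mean_nm_s,
                x$results$velocity$n))
  invisible(x)
}

#' Duty-ratio predictions as a printed report
#'
#' Convenience front end to [filament_duty_ratio()] and
#' [min_motors_for_processivity()], echoing the inputs.
#'
#' @param r Single-motor duty ratio.
#' @param n Motor count for a filament duty-ratio prediction (optional).
#' @param target Target filament duty ratio for a minimum-motor-number
#'   prediction (optional).
#' @return Invisibly, a list with the computed values.
#' @export
predict_report <- function(r, n = NULL, target = NULL) {
  out <- list(r = r)
  cat(sprintf("Single-motor duty ratio r = %g\n", r))
  if (!is.null(n)) {
    rf <- filament_duty_ratio(r, n)
    out$n <- n; out$rf <- rf
    cat(sprintf("  filament duty ratio with n = %d motors: rf = %.4f (%.1f at one decimal)\n",
                as.integer(n), rf, round(rf, 1)))
  }
  if (!is.null(target)) {
    nmin <- min_motors_for_processivity(r, target)
    out$target <- target; out$min_motors <- nmin
    cat(sprintf("  minimum motors for rf >= %g: %d\n", target, nmin))
  }
  invisible(out)
}
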