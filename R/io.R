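#' Run configuration with reference-workflow defaults
#'
#' Collects every tunable of the pipeline in one round-trippable list:
#' the pacing protocols (1 Hz; 500 control beats, 150 drug beats), the
#' conductance sampling ranges and experimental calibration windows, the risk
#' thresholds (EMw shortening -10%, APD90 prolongation +6%, RA in >= 1 model,
#' 97% RA saturation), the tested concentration multiples (1, 3, 10, 30,
#' 100x EFTPCmax), the block-scan levels, solver tolerances, and seeds.
#'
#' @param ... named overrides of any top-level entry.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    population_size = 150,
    control_beats = 500,
    drug_beats = 150,
    cl = 1000, stim_amp = -80, stim_dur = 0.5,
    ranges = sampling_ranges(),
    windows = calibration_windows(),
    multiples = c(1, 3, 10, 30, 100),
    scan_levels = c(0, 0.25, 0.5, 0.75, 1),
    emw_threshold = -10,
    apd_threshold = 6,
    ra_min_models = 1,
    ra_saturation = 0.97,
    emw_denominator_floor = 1,
    solver = solver_settings(),
    seed = 1L,
    sampling_method = "uniform")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$emw_threshold < 0, cfg$apd_threshold > 0,
            cfg$ra_min_models >= 1,
            cfg$ra_saturation > 0, cfg$ra_saturation <= 1)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg, p))`
#' reproduces `cfg`.
#'
#' @param cfg a [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$ranges <- lapply(raw$ranges, as.numeric)
  raw$windows <- lapply(raw$windows, as.numeric)
  raw$solver <- lapply(raw$solver, as.numeric)
  do.call(run_config, raw)
}

#' Protocols implied by a run configuration
#'
#' @param cfg a [run_config()].
#' @return list with `control` and `drug` [stimulus_protocol()]s.
#' @export
config_protocols <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  list(control = stimulus_protocol(cl = cfg$cl, beats = cfg$control_beats,
                                   stim_amp = cfg$stim_amp,
                                   stim_dur = cfg$stim_dur),
       drug = stimulus_protocol(cl = cfg$cl, beats = cfg$drug_beats,
                                stim_amp = cfg$stim_amp,
                                stim_dur = cfg$stim_dur))
}

#' Write trial artifacts to a directory
#'
#' Writes `per_model.csv` (one row per model x concentration),
#' `summary.csv` (one row per concentration) and `manifest.json` (drug record,
#' scores under both criteria).
#'
#' @param trial a `trial_result`.
#' @param dir output directory (created if needed).
#' @export
write_trial_result <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$per_model, file.path(dir, "per_model.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    drug = list(name = trial$drug$name, category = trial$drug$category,
                eftpc_max_uM = trial$drug$eftpc_max,
                channels = trial$drug$channels),
    multiples = trial$multiples,
    tdp_score_ra_emw = trial_tdp_score(trial, include_emw = TRUE),
    tdp_score_ra_only = trial_tdp_score(trial, include_emw = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
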