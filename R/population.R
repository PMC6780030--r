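#' Conductance sampling ranges for the control population
#'
#' Per-parameter \[low, high\] bounds, as fractions of the baseline model
#' values, inside which the nine conductance scaling factors are drawn. The
#' defaults are the published variability ranges optimised for pro-arrhythmic
#' ionic profiles: the main repolarising currents may only be down-regulated
#' (GKr 45-100%, GKs 0-100%, GNaK 30-100%) while the main inward currents may
#' only be up-regulated (GNaL, GNCX, GCaL 100-200%).
#'
#' @param ... named length-2 numeric vectors overriding individual ranges,
#'   e.g. `sKr = c(0.45, 1)`.
#' @return named list of nine \[low, high\] ranges.
#' @export
sampling_ranges <- function(...) {
  rng <- list(sNa  = c(0.30, 2.00), sNaL = c(1.00, 2.00),
              sto  = c(0.00, 2.00), sKr  = c(0.45, 1.00),
              sKs  = c(0.00, 1.00), sK1  = c(0.30, 2.00),
              sNCX = c(1.00, 2.00), sNaK = c(0.30, 1.00),
              sCaL = c(1.00, 2.00))
  over <- list(...)
  bad <- setdiff(names(over), names(rng))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  rng[names(over)] <- over
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] < 0 || r[1] > r[2])
      stop("invalid range for ", nm)
  }
  rng
}

#' Experimental biomarker calibration windows
#'
#' Per-biomarker \[min, max\] acceptance bounds from undiseased human
#' ventricular AP and Ca2+ transient recordings. A model is accepted into the
#' control population only if all nine biomarkers fall inside these windows
#' (and it shows no repolarisation/depolarisation abnormality in control).
#'
#' @param ... named length-2 numeric vectors overriding individual windows.
#' @return named list of \[min, max\] windows (ms, V/s or mV as appropriate).
#' @export
calibration_windows <- function(...) {
  win <- list(APD40 = c(85, 320), APD50 = c(110, 350), APD90 = c(180, 440),
              Tri90_40 = c(50, 150), dVdtMAX = c(100, 1000),
              Vpeak = c(10, 55), RMP = c(-95, -80),
              CTD50 = c(120, 420), CTD90 = c(220, 785))
  over <- list(...)
  bad <- setdiff(names(over), names(win))
  if (length(bad)) stop("unknown biomarkers: ", paste(bad, collapse = ", "))
  win[names(over)] <- over
  for (nm in names(win)) {
    w <- win[[nm]]
    if (length(w) != 2 || any(!is.finite(w)) || w[1] > w[2])
      stop("invalid window for ", nm)
  }
  win
}

#' Sample candidate conductance-scaling sets
#'
#' Draws `n` scaling sets with each coordinate independent and uniform within
#' its range (Latin hypercube optionally, which stratifies each coordinate
#' into `n` equal slices). Reproducible under a fixed seed.
#'
#' @param n number of candidate models.
#' @param ranges see [sampling_ranges()].
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @param method `"uniform"` (default) or `"lhs"`.
#' @return data.frame of `n` rows x 9 scaling columns.
#' @export
sample_population <- function(n, ranges = sampling_ranges(), seed = NULL,
                              method = c("uniform", "lhs")) {
  method <- match.arg(method)
  if (n < 1) stop("population size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(lo, hi) {
    u <- if (method == "uniform") stats::runif(n)
         else (sample.int(n) - stats::runif(n)) / n
    lo + u * (hi - lo)
  }
  out <- as.data.frame(lapply(ranges, function(r) draw(r[1], r[2])))
  rownames(out) <- NULL
  out
}

#' Simulate candidates to steady state and calibrate against experiment
#'
#' Each candidate is paced from the published resting state under the control
#' protocol; the last beat's full biomarker set is extracted and the model is
#' accepted when every biomarker lies inside the calibration windows and the
#' control beat shows no repolarisation or depolarisation abnormality.
#' Rejected models stay in the object with a reason code; integration failures
#' are recorded as rejections, never silently dropped.
#'
#' @param candidates data.frame of scaling sets from [sample_population()].
#' @param windows see [calibration_windows()].
#' @param protocol control pacing protocol; the reference workflow uses
#'   500 beats at 1 Hz.
#' @param solver see [solver_settings()].
#' @param verbose print per-model progress.
#' @return object of class `ap_population`: list with `scalings`,
#'   `biomarkers` (one row per candidate), `states` (matrix of steady states),
#'   `accepted` (logical), `reject_reason` (character), and `provenance`.
#' @export
calibrate <- function(candidates, windows = calibration_windows(),
                      protocol = stimulus_protocol(beats = 500),
                      solver = solver_settings(), verbose = FALSE) {
  n <- nrow(candidates)
  stopifnot(n >= 1, all(names(sampling_ranges()) %in% names(candidates)))
  bm_list <- vector("list", n)
  states <- matrix(NA_real_, nrow = n, ncol = 41,
                   dimnames = list(NULL, names(ord_initial_state())))
  accepted <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    s <- as.numeric(candidates[i, names(sampling_ranges())])
    tr <- suppressWarnings(
      simulate_paced(scalings = s, protocol = protocol, solver = solver,
                     model_id = sprintf("m%03d", i)))
    if (!tr$ok) {
      bm_list[[i]] <- trace_biomarkers(tr)
      reason[i] <- sprintf("solver_failure@beat%d", tr$fail_beat)
      next
    }
    states[i, ] <- tr$final_state
    bm <- trace_biomarkers(tr)
    bm_list[[i]] <- bm
    if (bm$RA || bm$DA) { reason[i] <- "abnormal_control_beat"; next }
    out_of <- character(0)
    for (nm in names(windows)) {
      val <- bm[[nm]][1]
      if (is.na(val) || val < windows[[nm]][1] || val > windows[[nm]][2])
        out_of <- c(out_of, nm)
    }
    if (length(out_of)) {
      reason[i] <- paste0("outside:", paste(out_of, collapse = "+"))
    } else {
      accepted[i] <- TRUE
      reason[i] <- "accepted"
    }
    if (verbose)
      message(sprintf("model %d/%d: %s", i, n, reason[i]))
  }
  bm <- do.call(rbind, bm_list)
  bm$model_id <- sprintf("m%03d", seq_len(n))
  structure(list(scalings = candidates, biomarkers = bm, states = states,
                 accepted = accepted, reject_reason = reason,
                 provenance = list(windows = windows, protocol = protocol,
                                   solver = solver, n_candidates = n,
                                   n_accepted = sum(accepted))),
            class = "ap_population")
}

#' @export
print.ap_population <- function(x, ...) {
  cat(sprintf("<ap_population: %d/%d models accepted (%.0f%%)>\n",
              sum(x$accepted), length(x$accepted),
              100 * mean(x$accepted)))
  invisible(x)
}

#' Restrict a population to its accepted models
#'
#' @param pop an `ap_population`.
#' @return an `ap_population` containing only accepted models. Recalibration
#'   of the result is a no-op (acceptance is idempotent).
#' @export
accepted_models <- function(pop) {
  stopifnot(inherits(pop, "ap_population"))
  keep <- pop$accepted
  reset <- function(df) { rownames(df) <- NULL; df }
  structure(list(scalings = reset(pop$scalings[keep, , drop = FALSE]),
                 biomarkers = reset(pop$biomarkers[keep, , drop = FALSE]),
                 states = pop$states[keep, , drop = FALSE],
                 accepted = pop$accepted[keep],
                 reject_reason = pop$reject_reason[keep],
                 provenance = pop$provenance),
            class = "ap_population")
}

#' Build a calibrated control population in one call
#'
#' Samples `n` candidates in the default (or supplied) ranges, paces each to
#' steady state and calibrates against the experimental windows.
#'
#' @inheritParams sample_population
#' @inheritParams calibrate
#' @export
build_population <- function(n = 150, ranges = sampling_ranges(),
                             windows = calibration_windows(),
                             protocol = stimulus_protocol(beats = 500),
                             solver = solver_settings(), seed = NULL,
                             method = "uniform", verbose = FALSE) {
  cand <- sample_population(n, ranges = ranges, seed = seed, method = method)
  pop <- calibrate(cand, windows = windows, protocol = protocol,
                   solver = solver, verbose = verbose)
  pop$provenance$seed <- seed
  pop$provenance$ranges <- ranges
  pop$provenance$method <- method
  pop
}

#' Save / load a population directory
#'
#' A population is stored as plain-text artifacts: `scalings.csv`,
#' `biomarkers.csv`, `states.csv` (steady states, one row per model) and a
#' `manifest.json` with acceptance flags and provenance.
#'
#' @param pop an `ap_population`.
#' @param dir directory (created if needed).
#' @export
save_population <- function(pop, dir) {
  stopifnot(inherits(pop, "ap_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pop$scalings, file.path(dir, "scalings.csv"),
                   row.names = FALSE)
  utils::write.csv(pop$biomarkers, file.path(dir, "biomarkers.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pop$states), file.path(dir, "states.csv"),
                   row.names = FALSE)
  manifest <- list(accepted = pop$accepted,
                   reject_reason = pop$reject_reason,
                   provenance = pop$provenance[c("n_candidates", "n_accepted",
                                                 "seed", "method")],
                   windows = pop$provenance$windows,
                   protocol = unclass(pop$provenance$protocol),
                   solver = pop$provenance$solver)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_population
#' @export
load_population <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  prot <- stimulus_protocol(cl = man$protocol$cl, beats = man$protocol$beats,
                            stim_amp = man$protocol$stim_amp,
                            stim_dur = man$protocol$stim_dur)
  structure(list(
    scalings = utils::read.csv(file.path(dir, "scalings.csv")),
    biomarkers = utils::read.csv(file.path(dir, "biomarkers.csv")),
    states = as.matrix(utils::read.csv(file.path(dir, "states.csv"))),
    accepted = man$accepted,
    reject_reason = man$reject_reason,
    provenance = list(windows = lapply(man$windows, as.numeric),
                      protocol = prot, solver = man$solver,
                      n_candidates = man$provenance$n_candidates,
                      n_accepted = man$provenance$n_accepted,
                      seed = man$provenance$seed,
                      method = man$provenance$method)),
    class = "ap_population")
}
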