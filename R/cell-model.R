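#' Ionic conductance scaling factors
#'
#' Construct the vector of nine multiplicative scaling factors that defines one
#' model of a population. Each factor multiplies the corresponding maximal
#' conductance (or permeability) of the baseline endocardial O'Hara-Rudy model:
#' GNa, GNaL, Gto, GKr, GKs, GK1, GNCX, GNaK, and PCa (L-type Ca2+).
#'
#' @param sNa,sNaL,sto,sKr,sKs,sK1,sNCX,sNaK,sCaL non-negative dimensionless
#'   factors (1 = baseline).
#' @return named numeric vector of length 9.
#' @export
#' @examples
#' ionic_scalings()            # baseline model
#' ionic_scalings(sKr = 0.5)   # half the IKr conductance
ionic_scalings <- function(sNa = 1, sNaL = 1, sto = 1, sKr = 1, sKs = 1,
                           sK1 = 1, sNCX = 1, sNaK = 1, sCaL = 1) {
  s <- c(sNa = sNa, sNaL = sNaL, sto = sto, sKr = sKr, sKs = sKs,
         sK1 = sK1, sNCX = sNCX, sNaK = sNaK, sCaL = sCaL)
  if (any(!is.finite(s)) || any(s < 0))
    stop("scaling factors must be finite and >= 0")
  s
}

#' Fractional channel block
#'
#' Per-channel fractional block b in [0,1]. The effective conductance of a
#' channel is s * (1 - b): a block of 1 silences the current completely.
#' Channels without a value default to no block.
#'
#' @param INa,INaL,Ito,IKr,IKs,IK1,ICaL block fractions in \[0,1\].
#' @return named numeric vector of length 7.
#' @export
#' @examples
#' block_fractions(IKr = 0.5)  # 50% IKr block
block_fractions <- function(INa = 0, INaL = 0, Ito = 0, IKr = 0, IKs = 0,
                            IK1 = 0, ICaL = 0) {
  b <- c(INa = INa, INaL = INaL, Ito = Ito, IKr = IKr, IKs = IKs,
         IK1 = IK1, ICaL = ICaL)
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1))
    stop("block fractions must lie in [0,1]")
  b
}

#' Pacing protocol
#'
#' Square-pulse current-clamp pacing. Defaults follow the original ORd
#' publication: -80 uA/uF for 0.5 ms at the start of each 1000-ms cycle.
#'
#' @param cl cycle length in ms (> 0).
#' @param beats number of beats (>= 1). The control pre-pacing protocol of the
#'   workflow uses 500 beats; drug runs use 150.
#' @param stim_amp stimulus amplitude in uA/uF (negative = depolarising).
#' @param stim_dur stimulus duration in ms.
#' @export
stimulus_protocol <- function(cl = 1000, beats = 500, stim_amp = -80,
                              stim_dur = 0.5) {
  if (cl <= 0) stop("cycle length must be > 0")
  if (beats < 1) stop("at least one beat is required")
  if (stim_dur < 0 || stim_dur >= cl) stop("stimulus duration must lie in [0, cl)")
  structure(list(cl = cl, beats = as.integer(beats), stim_amp = stim_amp,
                 stim_dur = stim_dur), class = "stimulus_protocol")
}

#' Explicit-integrator settings
#'
#' The solver takes Rush-Larsen exponential steps for gating variables and
#' Heun (second-order predictor-corrector) steps for voltage, concentrations
#' and CaMK, with the step size adapted so each step changes the membrane
#' voltage by at most `dv_step` mV (bounded by `dt_min` and `dt_max`).
#' Halving all three settings is the grid-refinement direction used by the
#' convergence checks; at the defaults, APD90 and CTD90 are converged to
#' better than 1 ms.
#'
#' @param dt_min,dt_max step bounds in ms.
#' @param dv_step target voltage increment per step in mV.
#' @export
solver_settings <- function(dt_min = 0.005, dt_max = 1.0, dv_step = 0.2) {
  if (dt_min <= 0 || dt_max < dt_min || dv_step <= 0)
    stop("invalid solver settings")
  list(dt_min = dt_min, dt_max = dt_max, dv_step = dv_step)
}

#' Initial state of the endocardial ORd model
#'
#' The published resting initial conditions of the O'Hara-Rudy dynamic model
#' (endocardial variant). Models are paced from here to their own steady state.
#'
#' @return named numeric vector of 41 state variables (voltage in mV,
#'   gates dimensionless, concentrations in mM).
#' @export
ord_initial_state <- function() ord_default_state_cpp()

#' Time derivatives of the ORd state vector
#'
#' Evaluate the right-hand side of the model at one state, with each targeted
#' maximal conductance multiplied by s_X * (1 - b_X). The instantaneous current
#' decomposition (uA/uF; SR fluxes in mM/ms) is attached as attribute
#' `"currents"`.
#'
#' @param state named state vector as from [ord_initial_state()].
#' @param scalings see [ionic_scalings()].
#' @param blocks see [block_fractions()].
#' @param Ist externally applied stimulus current in uA/uF.
#' @return named derivative vector (per ms) with attribute `"currents"`.
#' @export
ord_rhs <- function(state, scalings = ionic_scalings(),
                    blocks = block_fractions(), Ist = 0) {
  ord_rhs_cpp(as.numeric(state), as.numeric(scalings), as.numeric(blocks), Ist)
}

#' Simulate paced beats and return the final-beat trace
#'
#' Integrates the scaled, blocked ORd model beat-to-beat with state carry-over
#' and returns the last beat's voltage and intracellular Ca2+ series on the
#' solver's adaptive grid (dense during the upstroke), together with the final
#' state for trial restarts.
#'
#' @param scalings,blocks see [ionic_scalings()], [block_fractions()].
#' @param protocol a [stimulus_protocol()].
#' @param init initial state vector; defaults to the published resting state.
#' @param solver see [solver_settings()].
#' @param model_id optional identifier carried into error messages and traces.
#' @param fallback retry once at four-fold tighter voltage resolution when the
#'   integration fails (a few low-repolarisation-reserve parameter corners
#'   need it; genuinely divergent dynamics still fail and are reported).
#' @return object of class `paced_trace`: list with `time` (ms, from the last
#'   beat's stimulus onset), `v` (mV), `cai` (mM), `final_state`, `ok`
#'   (FALSE when the integration failed; the trace is then empty), `fail_beat`,
#'   `protocol`, and `model_id`.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_paced(protocol = stimulus_protocol(beats = 5))
#' range(tr$v)
#' }
simulate_paced <- function(scalings = ionic_scalings(),
                           blocks = block_fractions(),
                           protocol = stimulus_protocol(),
                           init = ord_initial_state(),
                           solver = solver_settings(),
                           model_id = NA_character_,
                           fallback = TRUE) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (length(init) != 41L) stop("initial state must have 41 components")
  bad <- which(!is.finite(as.numeric(init)))
  if (length(bad))
    stop("non-finite initial state component: ",
         paste(names(ord_initial_state())[bad], collapse = ", "))
  res <- ord_simulate_cpp(as.numeric(init), as.numeric(scalings),
                          as.numeric(blocks), protocol$cl, protocol$beats,
                          protocol$stim_amp, protocol$stim_dur,
                          solver$dt_min, solver$dt_max, solver$dv_step)
  if (res$status != 0L && fallback) {
    tight <- solver_settings(dt_min = solver$dt_min / 2,
                             dt_max = solver$dt_max,
                             dv_step = solver$dv_step / 4)
    res <- ord_simulate_cpp(as.numeric(init), as.numeric(scalings),
                            as.numeric(blocks), protocol$cl, protocol$beats,
                            protocol$stim_amp, protocol$stim_dur,
                            tight$dt_min, tight$dt_max, tight$dv_step)
  }
  if (res$status != 0L)
    warning(sprintf("integration failed for model %s at beat %d",
                    ifelse(is.na(model_id), "<unnamed>", model_id),
                    res$fail_beat))
  structure(list(time = res$time, v = res$v, cai = res$cai,
                 final_state = res$final_state,
                 ok = res$status == 0L, fail_beat = res$fail_beat,
                 protocol = protocol, model_id = model_id),
            class = "paced_trace")
}

#' Build a paced_trace from raw series
#'
#' Wrap externally supplied (or synthetic) time/voltage/Ca2+ series in the
#' trace container used by the biomarker functions. Time must start at the
#' stimulus onset of the beat and be strictly increasing.
#'
#' @param time time grid in ms.
#' @param v voltage series in mV.
#' @param cai intracellular Ca2+ series in mM (optional).
#' @param cl cycle length metadata in ms.
#' @param model_id optional identifier.
#' @export
as_paced_trace <- function(time, v, cai = NULL, cl = max(time),
                           model_id = NA_character_) {
  if (length(time) != length(v)) stop("time and v must have equal length")
  if (!is.null(cai) && length(cai) != length(v))
    stop("cai must match the length of v")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = time, v = v, cai = cai, final_state = NULL,
                 ok = TRUE, fail_beat = -1L,
                 protocol = stimulus_protocol(cl = cl, beats = 1),
                 model_id = model_id),
            class = "paced_trace")
}

#' @export
print.paced_trace <- function(x, ...) {
  cat(sprintf("<paced_trace%s: %d samples over %.0f ms, V in [%.1f, %.1f] mV%s>\n",
              ifelse(is.na(x$model_id), "", paste0(" ", x$model_id)),
              length(x$time),
              if (length(x$time)) max(x$time) else 0,
              if (length(x$v)) min(x$v) else NA, if (length(x$v)) max(x$v) else NA,
              if (x$ok) "" else " [FAILED]"))
  invisible(x)
}

#' Serialise a model state vector to JSON for later restarts
#'
#' @param state named 41-component state vector.
#' @param path JSON path.
#' @export
write_model_state <- function(state, path) {
  stopifnot(length(state) == 41L)
  jsonlite::write_json(as.list(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_state
#' @export
read_model_state <- function(path) {
  x <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  if (length(x) != 41L) stop("state file must hold 41 components")
  x[names(ord_initial_state())]
}

#' Write / read a trace as a delimited table with a JSON sidecar
#'
#' The table holds `time`, `v`, `cai`; the sidecar records the pacing protocol
#' and model id so a trace round-trips losslessly.
#'
#' @param trace a `paced_trace`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_trace` returns `path` invisibly; `read_trace` a `paced_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "paced_trace"))
  df <- data.frame(time = trace$time, v = trace$v,
                   cai = if (is.null(trace$cai)) NA_real_ else trace$cai)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model_id = trace$model_id, cl = trace$protocol$cl,
               beats = trace$protocol$beats,
               stim_amp = trace$protocol$stim_amp,
               stim_dur = trace$protocol$stim_dur,
               cai_units = "mM")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tr <- as_paced_trace(df$time, df$v,
                       cai = if (all(is.na(df$cai))) NULL else df$cai,
                       cl = meta$cl, model_id = meta$model_id)
  tr$protocol <- stimulus_protocol(cl = meta$cl, beats = meta$beats,
                                   stim_amp = meta$stim_amp,
                                   stim_dur = meta$stim_dur)
  tr
}
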