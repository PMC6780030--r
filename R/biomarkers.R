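## Biomarker extraction from a single-beat trace.
## All durations are measured from the instant of maximum upstroke velocity;
## threshold crossings are located by linear interpolation between samples.

# first downward crossing of `series` below `thr`, searching from index `from`;
# returns interpolated time or NA
.cross_down <- function(time, series, thr, from) {
  n <- length(series)
  if (from >= n) return(NA_real_)
  idx <- which(series[(from + 1):n] <= thr)
  if (!length(idx)) return(NA_real_)
  i <- from + idx[1]
  if (series[i - 1] == series[i]) return(time[i])
  time[i - 1] + (thr - series[i - 1]) * (time[i] - time[i - 1]) /
    (series[i] - series[i - 1])
}

# index and value of the maximum forward-difference derivative (mV/ms == V/s)
.upstroke <- function(time, v) {
  dv <- diff(v) / diff(time)
  i <- which.max(dv)
  list(idx = i, t = time[i], dvdt = dv[i])
}

#' Action-potential biomarkers
#'
#' Extract the seven AP biomarkers from one beat: APD40/50/90 (ms),
#' triangulation Tri90_40 = APD90 - APD40 (ms), dV/dtMAX (V/s), Vpeak (mV) and
#' RMP (mV, the pre-stimulus voltage). APDxx is the time from the instant of
#' maximum upstroke velocity to the first downward crossing of
#' Vpeak - (xx/100) * (Vpeak - RMP). When no upstroke is detected (dV/dtMAX
#' below `dvdt_floor`) the AP biomarkers are invalid (NA) and the trace is a
#' depolarisation abnormality.
#'
#' @param trace a `paced_trace` spanning one full cycle with one stimulus.
#' @param dvdt_floor excitability floor in V/s below which no AP is scored.
#' @return one-row data.frame with columns APD40, APD50, APD90, Tri90_40,
#'   dVdtMAX, Vpeak, RMP.
#' @export
ap_biomarkers <- function(trace, dvdt_floor = 10) {
  stopifnot(inherits(trace, "paced_trace"))
  na <- data.frame(APD40 = NA_real_, APD50 = NA_real_, APD90 = NA_real_,
                   Tri90_40 = NA_real_, dVdtMAX = NA_real_,
                   Vpeak = NA_real_, RMP = NA_real_)
  if (!trace$ok || length(trace$time) < 3) return(na)
  t <- trace$time; v <- trace$v
  up <- .upstroke(t, v)
  rmp <- v[1]
  vpeak <- max(v)
  out <- na
  out$dVdtMAX <- up$dvdt; out$Vpeak <- vpeak; out$RMP <- rmp
  if (up$dvdt < dvdt_floor) return(out)
  amp <- vpeak - rmp
  ipk <- which.max(v)
  for (xx in c(40, 50, 90)) {
    thr <- vpeak - xx / 100 * amp
    tc <- .cross_down(t, v, thr, ipk)
    out[[paste0("APD", xx)]] <- if (is.na(tc)) NA_real_ else tc - up$t
  }
  out$Tri90_40 <- out$APD90 - out$APD40
  out
}

#' Calcium-transient biomarkers
#'
#' CTD50 and CTD90 (ms): the time from the instant of maximum upstroke
#' velocity until the Ca2+ transient has decayed 50% / 90% of the way from its
#' peak back to its pre-stimulus diastolic level. When the transient amplitude
#' is below `amp_floor` (e.g. under complete L-type Ca2+ block) the CTD fields
#' are invalid.
#'
#' @param trace a `paced_trace` with a Ca2+ series.
#' @param amp_floor minimal peak-minus-diastolic amplitude in mM.
#' @return one-row data.frame with columns CTD50, CTD90.
#' @export
cat_biomarkers <- function(trace, amp_floor = 1e-5) {
  stopifnot(inherits(trace, "paced_trace"))
  na <- data.frame(CTD50 = NA_real_, CTD90 = NA_real_)
  if (!trace$ok || is.null(trace$cai) || length(trace$time) < 3) return(na)
  t <- trace$time; ca <- trace$cai
  up <- .upstroke(t, trace$v)
  dia <- ca[1]
  ipk <- which.max(ca)
  if (ca[ipk] - dia < amp_floor) return(na)
  out <- na
  for (xx in c(50, 90)) {
    thr <- ca[ipk] - xx / 100 * (ca[ipk] - dia)
    tc <- .cross_down(t, ca, thr, ipk)
    out[[paste0("CTD", xx)]] <- if (is.na(tc)) NA_real_ else tc - up$t
  }
  out
}

#' Electromechanical window of a biomarker set
#'
#' EMw = CTD90 - APD90 (ms); may legitimately be negative. Undefined when
#' either duration is invalid.
#'
#' @param bset one-row data.frame with columns APD90 and CTD90.
#' @export
#' @examples
#' emw(data.frame(APD90 = 270, CTD90 = 450))  # 180 ms
emw <- function(bset) {
  if (is.na(bset$APD90[1]) || is.na(bset$CTD90[1])) return(NA_real_)
  bset$CTD90[1] - bset$APD90[1]
}

#' Detect repolarisation and depolarisation abnormalities
#'
#' A repolarisation abnormality (RA) is flagged when the voltage derivative
#' turns positive again after the plateau (an early-afterdepolarisation-like
#' reversal: dV/dt above `ra_tol` sustained for at least `ra_sustain` ms inside
#' the window from `ra_skip` ms after the upstroke until 90% repolarisation),
#' when the AP fails to repolarise below the 90% level before the end of
#' the beat, or - when a control reference is supplied - when the beat already
#' starts more than `rmp_shift` mV above the control resting potential (the
#' previous beat's repolarisation failure carried across the cycle boundary,
#' as in 2:1 responses under strong IKr block). A depolarisation abnormality
#' (DA) is flagged when a beat starting from a normal diastolic potential
#' fails to produce a normal upstroke (dV/dtMAX below `dvdt_floor` or Vpeak
#' below 0 mV).
#'
#' @param trace a `paced_trace`.
#' @param control_rmp optional control resting membrane potential (mV).
#' @param dvdt_floor excitability floor (V/s).
#' @param ra_tol derivative-reversal tolerance (mV/ms, i.e. V/s).
#' @param ra_sustain minimal duration of the reversal (ms).
#' @param ra_skip detection-window offset after the upstroke (ms).
#' @param rmp_shift diastolic elevation tolerance vs control (mV).
#' @return list with logical elements `ra` and `da`.
#' @export
detect_abnormalities <- function(trace, control_rmp = NULL, dvdt_floor = 10,
                                 ra_tol = 0.01, ra_sustain = 2,
                                 ra_skip = 50, rmp_shift = 20) {
  stopifnot(inherits(trace, "paced_trace"))
  if (!trace$ok || length(trace$time) < 3)
    return(list(ra = NA, da = NA))   # failed run: flags are undefined
  t <- trace$time; v <- trace$v
  up <- .upstroke(t, v)
  rmp <- v[1]; vpeak <- max(v)
  # an elevated diastolic start means the previous beat never repolarised:
  # a repolarisation failure, not a depolarisation abnormality
  if (!is.null(control_rmp) && is.finite(control_rmp) &&
      rmp > control_rmp + rmp_shift)
    return(list(ra = TRUE, da = FALSE))
  if (up$dvdt < dvdt_floor || vpeak < 0)
    return(list(ra = FALSE, da = TRUE))

  thr90 <- vpeak - 0.9 * (vpeak - rmp)
  t90 <- .cross_down(t, v, thr90, which.max(v))
  if (is.na(t90)) return(list(ra = TRUE, da = FALSE))  # never repolarises

  lo <- up$t + ra_skip
  if (lo >= t90) return(list(ra = FALSE, da = FALSE))
  sel <- which(t >= lo & t <= t90)
  if (length(sel) < 3) return(list(ra = FALSE, da = FALSE))
  tt <- t[sel]; vv <- v[sel]
  dv <- diff(vv) / diff(tt)
  pos <- dv > ra_tol
  # accumulate the duration of consecutive positive-derivative segments
  run <- 0
  seg <- diff(tt)
  for (i in seq_along(pos)) {
    run <- if (pos[i]) run + seg[i] else 0
    if (run >= ra_sustain) return(list(ra = TRUE, da = FALSE))
  }
  list(ra = FALSE, da = FALSE)
}

#' Full biomarker set for one trace
#'
#' Combines [ap_biomarkers()], [cat_biomarkers()], the EMw, and the RA/DA
#' flags into one row. The EMw is set to NA whenever RA or DA is flagged or
#' either duration is invalid.
#'
#' @inheritParams detect_abnormalities
#' @param ... passed on to [detect_abnormalities()].
#' @return one-row data.frame with columns APD40, APD50, APD90, Tri90_40,
#'   dVdtMAX, Vpeak, RMP, CTD50, CTD90, EMw, RA, DA.
#' @export
trace_biomarkers <- function(trace, control_rmp = NULL, ...) {
  ap <- ap_biomarkers(trace)
  ct <- cat_biomarkers(trace)
  ab <- detect_abnormalities(trace, control_rmp = control_rmp, ...)
  out <- cbind(ap, ct)
  out$EMw <- if (isTRUE(ab$ra) || isTRUE(ab$da)) NA_real_ else emw(out)
  out$RA <- ab$ra
  out$DA <- ab$da
  out
}

#' Drug-induced percent biomarker changes
#'
#' Percent change of EMw, APD90 and CTD90 of a drugged beat relative to the
#' same model's control. Shortening is negative. A change is NA when either
#' biomarker is invalid; the EMw change is additionally NA when the control
#' EMw magnitude is below `emw_denominator_floor` ms (degenerate denominator).
#'
#' @param control,drug one-row biomarker data.frames from [trace_biomarkers()].
#' @param emw_denominator_floor minimal |control EMw| in ms.
#' @return one-row data.frame with columns dEMw, dAPD90, dCTD90 (percent).
#' @export
delta_biomarkers <- function(control, drug, emw_denominator_floor = 1) {
  pc <- function(a, b) {
    if (is.na(a) || is.na(b) || a == 0) NA_real_ else 100 * (b - a) / a
  }
  d_emw <- if (!is.na(control$EMw[1]) &&
               abs(control$EMw[1]) < emw_denominator_floor) NA_real_
           else pc(control$EMw[1], drug$EMw[1])
  data.frame(dEMw = d_emw,
             dAPD90 = pc(control$APD90[1], drug$APD90[1]),
             dCTD90 = pc(control$CTD90[1], drug$CTD90[1]))
}
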