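## Synthetic compendia and trace fixtures. These emulate the *schema* and the
## pharmacological archetypes of a real IC50/Hill drug table; they are
## synthetic stand-ins, not the proprietary values of any published compendium.

.ARCHETYPES <- c("pure_hERG", "hERG_plus_CaL", "NaL_mitigated",
                 "Na_dominant", "inert")

# potency ratios IC50/EFTPCmax per channel (h = 1 throughout):
#  - pure_hERG: IC50(IKr) = EFTPCmax -> 91% IKr block at 10x (a dofetilide-like
#    selective hERG blocker; clearly torsadogenic)
#  - hERG_plus_CaL: verapamil-like balance calibrated so 3x EFTPCmax gives
#    ~25% IKr and ~40% ICaL block (ratios 9 and 4.5)
#  - NaL_mitigated: hERG block with comparable late-Na block; APD prolongation
#    is tempered but the EMw still shortens, so the compound stays risky
#  - Na_dominant: pure fast-Na block (mexiletine-like), labelled safe. Note:
#    at high multiples INa block unloads intracellular Na+, which boosts NCX
#    Ca2+ extrusion and shortens CTD90, so the EMw criterion tends to flag
#    this archetype - the classic false-positive mode of the biomarker
.archetype_potency <- function(archetype) {
  switch(archetype,
    pure_hERG     = list(channels = list(IKr = 1),
                         category = "known"),
    hERG_plus_CaL = list(channels = list(IKr = 9, ICaL = 4.5),
                         category = "NC"),
    NaL_mitigated = list(channels = list(IKr = 2, INaL = 2),
                         category = "known"),
    Na_dominant   = list(channels = list(INa = 10),
                         category = "unlisted"),
    inert         = list(channels = list(),
                         category = "unlisted"),
    stop("unknown archetype: ", archetype))
}

#' Generate a synthetic drug compendium
#'
#' Builds reproducible [drug_record()]s from pharmacological archetypes:
#' a pure hERG blocker, a balanced hERG + L-type Ca2+ blocker (verapamil-like:
#' ~25% IKr and ~40% ICaL block at 3x EFTPCmax), a hERG blocker with
#' compensating late-Na block, an INa-dominant blocker, and an inert no-block
#' control. IC50s are set as multiples of EFTPCmax (1 uM) with a seeded
#' multiplicative jitter of up to `jitter` (fractional). Intended truth labels
#' follow the archetypes (hERG-driven compounds risky, the rest safe).
#'
#' @param archetypes which archetypes to include (default: one of each).
#' @param n_per compounds generated per archetype.
#' @param seed integer RNG seed.
#' @param jitter maximal fractional IC50 jitter (0 disables).
#' @param eftpc_max EFTPCmax assigned to every compound (uM).
#' @return named list of `drug_record`s.
#' @export
#' @examples
#' comp <- make_compendium(seed = 1)
#' drug_to_blocks(comp[["pure_hERG_1"]], 10)
make_compendium <- function(archetypes = .ARCHETYPES, n_per = 1, seed = 1,
                            jitter = 0.1, eftpc_max = 1) {
  stopifnot(all(archetypes %in% .ARCHETYPES), n_per >= 1, jitter >= 0,
            jitter < 1)
  set.seed(seed)
  out <- list()
  for (a in archetypes) {
    pot <- .archetype_potency(a)
    if (!length(pot$channels) && pot$category != "unlisted")
      stop("archetype without channels must be an unlisted (inert) control")
    for (k in seq_len(n_per)) {
      chans <- lapply(pot$channels, function(ratio) {
        j <- if (jitter > 0) 1 + stats::runif(1, -jitter, jitter) else 1
        c(ic50 = ratio * eftpc_max * j, h = 1)
      })
      nm <- sprintf("%s_%d", a, k)
      out[[nm]] <- drug_record(nm, channels = chans, eftpc_max = eftpc_max,
                               category = pot$category)
    }
  }
  out
}

# dense piecewise-linear trace from node lists
.pl_trace <- function(nodes_v, nodes_ca = NULL, t_end = 1000, dt = 0.1,
                      model_id = NA_character_) {
  t <- seq(0, t_end, by = dt)
  v <- stats::approx(nodes_v$t, nodes_v$v, xout = t, rule = 2)$y
  ca <- if (is.null(nodes_ca)) NULL
        else stats::approx(nodes_ca$t, nodes_ca$ca, xout = t, rule = 2)$y
  as_paced_trace(t, v, cai = ca, cl = t_end, model_id = model_id)
}

#' Synthetic single-beat trace fixtures with known biomarkers
#'
#' Piecewise-linear AP and Ca2+ transient fixtures whose biomarkers follow
#' from elementary geometry, for exercising the biomarker extractors and the
#' abnormality detector without running the cell model:
#' \describe{
#'   \item{linear_ap}{rise -85 to +35 mV over 0.2 ms at t = 0, linear fall
#'     back over 300 ms; Ca2+ from 0.1 to 1.1 uM decaying linearly over
#'     500 ms. APD90 = 270 ms, APD40 = 120 ms, APD50 = 150 ms,
#'     CTD50 = 250 ms, CTD90 = 450 ms, EMw = 180 ms.}
#'   \item{ead}{same AP with a 15-mV secondary depolarisation at 80%
#'     repolarisation - a repolarisation abnormality.}
#'   \item{non_repolarising}{repolarises only to -20 mV before the next
#'     stimulus - a repolarisation abnormality.}
#'   \item{no_upstroke}{no excitation (voltage stays near rest) - a
#'     depolarisation abnormality.}
#'   \item{noisy}{linear_ap plus seeded uniform noise below 0.1 mV; must not
#'     trigger the abnormality detector.}
#' }
#'
#' @param seed RNG seed for the noisy variant.
#' @param dt sample spacing in ms.
#' @return named list of `paced_trace` objects.
#' @export
make_trace_fixtures <- function(seed = 1, dt = 0.1) {
  rise <- 0.2
  ap <- list(t = c(0, rise, rise + 300, 1000), v = c(-85, 35, -85, -85))
  ca <- list(t = c(0, rise, rise + 500, 1000),
             ca = c(1e-4, 1.1e-3, 1e-4, 1e-4))
  fx <- list()
  fx$linear_ap <- .pl_trace(ap, ca, dt = dt, model_id = "linear_ap")

  # EAD bump: at 80% repolarisation (v = -61 mV, t = 240.2) climb 15 mV over
  # 20 ms, fall back over 20 ms, then resume the original ramp
  t80 <- rise + 0.8 * 300
  ead <- list(t = c(0, rise, t80, t80 + 20, t80 + 40, rise + 340, 1000),
              v = c(-85, 35, -61, -46, -61, -85, -85))
  fx$ead <- .pl_trace(ead, ca, dt = dt, model_id = "ead")

  nr <- list(t = c(0, rise, rise + 300, 1000), v = c(-85, 35, -20, -20))
  fx$non_repolarising <- .pl_trace(nr, ca, dt = dt,
                                   model_id = "non_repolarising")

  da <- list(t = c(0, 1, 50, 1000), v = c(-85, -82, -85, -85))
  fx$no_upstroke <- .pl_trace(da, ca, dt = dt, model_id = "no_upstroke")

  set.seed(seed)
  noisy <- fx$linear_ap
  noisy$v <- noisy$v + stats::runif(length(noisy$v), -0.05, 0.05)
  noisy$model_id <- "noisy"
  fx$noisy <- noisy
  fx
}
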