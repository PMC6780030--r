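.CHANNELS <- c("INa", "INaL", "Ito", "IKr", "IKs", "IK1", "ICaL")

#' Fractional block from the pore-block model
#'
#' Concentration-dependent fractional channel block under the simple
#' pore-block (Hill) model: the remaining conductance is
#' 1 / (1 + (C/IC50)^h), so the block fraction is 1 minus that.
#'
#' @param concentration drug concentration in uM (>= 0), vectorised.
#' @param ic50 half-maximal inhibitory concentration in uM (> 0).
#' @param h Hill coefficient (> 0).
#' @return block fraction(s) in \[0,1\].
#' @export
#' @examples
#' block_fraction(1, 1, 2)    # C = IC50 -> 0.5 for any h
#' block_fraction(3, 1, 1)    # 0.75
block_fraction <- function(concentration, ic50, h) {
  if (any(ic50 <= 0) || any(h <= 0)) stop("IC50 and Hill coefficient must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  1 - 1 / (1 + (concentration / ic50)^h)
}

#' One compound of a drug compendium
#'
#' Per-channel IC50 (uM) and Hill coefficient for any subset of the seven
#' blockable channels, the maximal effective free therapeutic plasma
#' concentration (EFTPCmax, uM) and the clinical TdP risk category. Channels
#' without data contribute zero block.
#'
#' @param name compound name.
#' @param channels named list; each element a numeric vector
#'   `c(ic50 = ..., h = ...)` for one of INa, INaL, Ito, IKr, IKs, IK1, ICaL.
#' @param eftpc_max EFTPCmax in uM (> 0).
#' @param category TdP risk category: `"known"`, `"possible"`,
#'   `"conditional"`, `"NC"` (reviewed, not classified) or `"unlisted"`.
#' @export
#' @examples
#' drug_record("dofetilide-like",
#'             channels = list(IKr = c(ic50 = 0.005, h = 1)),
#'             eftpc_max = 0.002, category = "known")
drug_record <- function(name, channels = list(), eftpc_max,
                        category = c("known", "possible", "conditional",
                                     "NC", "unlisted")) {
  category <- match.arg(category)
  if (eftpc_max <= 0) stop("EFTPCmax must be > 0")
  bad <- setdiff(names(channels), .CHANNELS)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!all(c("ic50", "h") %in% names(v)))
      stop("channel ", ch, " needs named elements 'ic50' and 'h'")
    if (v[["ic50"]] <= 0 || v[["h"]] <= 0)
      stop("channel ", ch, ": IC50 and h must be > 0")
  }
  structure(list(name = name, channels = channels, eftpc_max = eftpc_max,
                 category = category), class = "drug_record")
}

#' Channel blocks of a drug at a concentration multiple
#'
#' Evaluates the pore-block model for every channel of a [drug_record()] at
#' C = multiple x EFTPCmax. Channels without IC50 data get zero block.
#'
#' @param drug a [drug_record()].
#' @param multiple concentration as a multiple of EFTPCmax (> 0).
#' @return a [block_fractions()] vector.
#' @export
drug_to_blocks <- function(drug, multiple) {
  stopifnot(inherits(drug, "drug_record"))
  if (multiple <= 0) stop("concentration multiple must be > 0")
  b <- block_fractions()
  conc <- multiple * drug$eftpc_max
  for (ch in names(drug$channels)) {
    v <- drug$channels[[ch]]
    b[[ch]] <- block_fraction(conc, v[["ic50"]], v[["h"]])
  }
  b
}

#' Write / read a drug compendium as a long CSV
#'
#' Schema: one row per drug-channel pair with columns `name`, `channel`,
#' `ic50_uM`, `hill`, `eftpc_max_uM`, `tdp_category`. Compounds without any
#' channel data (inert controls) carry a single row with an empty channel.
#'
#' @param drugs list of [drug_record()]s.
#' @param path CSV path.
#' @return `write_compendium` returns `path` invisibly; `read_compendium`
#'   a named list of `drug_record`s.
#' @export
write_compendium <- function(drugs, path) {
  rows <- lapply(drugs, function(d) {
    stopifnot(inherits(d, "drug_record"))
    if (!length(d$channels))
      return(data.frame(name = d$name, channel = NA_character_,
                        ic50_uM = NA_real_, hill = NA_real_,
                        eftpc_max_uM = d$eftpc_max, tdp_category = d$category))
    do.call(rbind, lapply(names(d$channels), function(ch)
      data.frame(name = d$name, channel = ch,
                 ic50_uM = d$channels[[ch]][["ic50"]],
                 hill = d$channels[[ch]][["h"]],
                 eftpc_max_uM = d$eftpc_max, tdp_category = d$category)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path) {
  df <- utils::read.csv(path)
  need <- c("name", "channel", "ic50_uM", "hill", "eftpc_max_uM",
            "tdp_category")
  if (!all(need %in% names(df)))
    stop("compendium must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$name), function(g) {
    chans <- list()
    for (k in seq_len(nrow(g))) {
      ch <- g$channel[k]
      if (is.na(ch) || !nzchar(ch)) next
      chans[[ch]] <- c(ic50 = g$ic50_uM[k], h = g$hill[k])
    }
    drug_record(g$name[1], channels = chans, eftpc_max = g$eftpc_max_uM[1],
                category = g$tdp_category[1])
  })
  out[unique(df$name)]
}

## Shared condition runner: apply fixed blocks to every model of a calibrated
## population, pace `beats` beats from each model's own control steady state,
## and compare the final beat with that model's control biomarkers.
.block_condition_run <- function(pop, blocks, beats, solver) {
  stopifnot(inherits(pop, "ap_population"))
  pop <- accepted_models(pop)
  n <- nrow(pop$scalings)
  if (n == 0) stop("population has no accepted models")
  cl <- pop$provenance$protocol$cl
  prot <- stimulus_protocol(cl = cl, beats = beats,
                            stim_amp = pop$provenance$protocol$stim_amp,
                            stim_dur = pop$provenance$protocol$stim_dur)
  rows <- vector("list", n)
  scol <- names(sampling_ranges())
  for (i in seq_len(n)) {
    ctrl <- pop$biomarkers[i, ]
    tr <- suppressWarnings(
      simulate_paced(scalings = as.numeric(pop$scalings[i, scol]),
                     blocks = blocks, protocol = prot,
                     init = pop$states[i, ], solver = solver,
                     model_id = ctrl$model_id))
    bm <- trace_biomarkers(tr, control_rmp = ctrl$RMP)
    dl <- delta_biomarkers(ctrl, bm)
    rows[[i]] <- data.frame(model_id = ctrl$model_id, ok = tr$ok,
                            RA = bm$RA, DA = bm$DA,
                            APD90 = bm$APD90, CTD90 = bm$CTD90, EMw = bm$EMw,
                            dEMw = dl$dEMw, dAPD90 = dl$dAPD90,
                            dCTD90 = dl$dCTD90)
  }
  do.call(rbind, rows)
}

.summarise_condition <- function(per_model, emw_threshold = -10,
                                 apd_threshold = 6) {
  n <- nrow(per_model)
  n_ra <- sum(per_model$RA, na.rm = TRUE)
  valid <- !is.na(per_model$dEMw)
  data.frame(
    n_tot = n,
    nRA = n_ra,
    nDA = sum(per_model$DA, na.rm = TRUE),
    n_valid_emw = sum(valid),
    nEMw = sum(per_model$dEMw[valid] < emw_threshold),
    frac_RA = n_ra / n,
    frac_EMw_short = sum(per_model$dEMw[valid] < emw_threshold) / n,
    frac_APD90_long = sum(per_model$dAPD90 > apd_threshold, na.rm = TRUE) / n,
    median_dEMw = if (any(valid)) stats::median(per_model$dEMw[valid])
                  else NA_real_,
    median_dAPD90 = if (any(!is.na(per_model$dAPD90)))
      stats::median(per_model$dAPD90, na.rm = TRUE) else NA_real_,
    median_dCTD90 = if (any(!is.na(per_model$dCTD90)))
      stats::median(per_model$dCTD90, na.rm = TRUE) else NA_real_)
}

#' Run a multi-concentration in silico drug trial
#'
#' For every accepted model and every concentration multiple: restart from the
#' model's own control steady state, apply the drug's pore-block fractions,
#' pace (150 beats at 1 Hz by default), extract biomarkers, flag RA/DA, and
#' compute percent changes against the same model's control. Per-model solver
#' failures are logged as invalid rows, never aborting the trial.
#'
#' @param pop calibrated `ap_population` (only accepted models are used).
#' @param drug a [drug_record()].
#' @param multiples tested concentrations as multiples of EFTPCmax.
#' @param beats drug-pacing beats per concentration.
#' @param solver see [solver_settings()].
#' @param emw_threshold percent EMw-shortening risk threshold (default -10).
#' @param apd_threshold percent APD90-prolongation threshold (default +6).
#' @return object of class `trial_result`: list with `drug`, `per_model`
#'   (one row per model x multiple) and `summary` (one row per multiple with
#'   nRA, nEMw, median changes and fractions).
#' @export
run_drug_trial <- function(pop, drug, multiples = c(1, 3, 10, 30, 100),
                           beats = 150, solver = solver_settings(),
                           emw_threshold = -10, apd_threshold = 6) {
  stopifnot(inherits(drug, "drug_record"))
  per <- list(); summ <- list()
  for (m in multiples) {
    pm <- .block_condition_run(pop, drug_to_blocks(drug, m), beats, solver)
    pm$multiple <- m
    per[[as.character(m)]] <- pm
    sm <- .summarise_condition(pm, emw_threshold, apd_threshold)
    sm$multiple <- m
    sm$concentration_uM <- m * drug$eftpc_max
    summ[[as.character(m)]] <- sm
  }
  structure(list(drug = drug, multiples = multiples,
                 per_model = do.call(rbind, per),
                 summary = do.call(rbind, summ)),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result: %s (%s), %d models x %d concentrations>\n",
              x$drug$name, x$drug$category,
              x$summary$n_tot[1], length(x$multiples)))
  print(x$summary[, c("multiple", "nRA", "nEMw", "median_dEMw",
                      "median_dAPD90")], row.names = FALSE)
  invisible(x)
}

#' Population response to one fixed block combination
#'
#' Applies a fixed [block_fractions()] vector to every accepted model of a
#' calibrated population (no IC50 conversion), paces each from its own control
#' steady state and summarises the drug-trial statistics for that single
#' condition. This is the shared engine behind [run_drug_trial()] and
#' [block_scan()].
#'
#' @inheritParams run_drug_trial
#' @param blocks a [block_fractions()] vector.
#' @return list with `per_model` (one row per model) and `summary` (one row).
#' @export
population_block_response <- function(pop, blocks, beats = 150,
                                      solver = solver_settings(),
                                      emw_threshold = -10,
                                      apd_threshold = 6) {
  pm <- .block_condition_run(pop, blocks, beats, solver)
  list(per_model = pm,
       summary = .summarise_condition(pm, emw_threshold, apd_threshold))
}

#' Channel-block sensitivity grid
#'
#' Applies every combination of fixed fractional blocks on the given channels
#' (by default IKr, ICaL and INaL at 0/25/50/75/100%, i.e. 125 combinations)
#' directly to every accepted model - no IC50 conversion - paces from each
#' model's control steady state, and summarises: median percent change of EMw
#' and APD90 across the population, and the fractions of models with RA, with
#' EMw shortening beyond threshold and with APD90 prolongation beyond
#' threshold. Cells where a summary is uncomputable (RA everywhere, or absent
#' Ca2+ transient under full L-type block) carry NA medians.
#'
#' @param pop calibrated `ap_population`.
#' @param levels block fractions applied to each channel.
#' @param channels character vector of channels to scan.
#' @param beats pacing beats per combination.
#' @param solver see [solver_settings()].
#' @inheritParams run_drug_trial
#' @return data.frame keyed by one block column per channel (e.g. `bIKr`),
#'   with the summary columns of [run_drug_trial()].
#' @export
block_scan <- function(pop, levels = c(0, 0.25, 0.5, 0.75, 1),
                       channels = c("IKr", "ICaL", "INaL"), beats = 150,
                       solver = solver_settings(),
                       emw_threshold = -10, apd_threshold = 6) {
  stopifnot(all(channels %in% .CHANNELS))
  grid <- expand.grid(rep(list(levels), length(channels)))
  names(grid) <- paste0("b", channels)
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    b <- block_fractions()
    for (j in seq_along(channels)) b[[channels[j]]] <- grid[k, j]
    pm <- .block_condition_run(pop, b, beats, solver)
    out[[k]] <- cbind(grid[k, , drop = FALSE],
                      .summarise_condition(pm, emw_threshold, apd_threshold))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
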