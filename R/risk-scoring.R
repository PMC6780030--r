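#' Classify a drug as risky or safe at one concentration
#'
#' Two criteria are provided. `"RA_only"`: the drug is risky if it provokes a
#' repolarisation abnormality in at least one model of the population.
#' `"RA_plus_EMw"`: risky if it shortens the median EMw by more than 10%
#' (median dEMw < -10, strict) or provokes RA in at least one model. Drugs
#' with RA in more than 97% of the population (three computable models or
#' fewer) are risky by construction even though no median can be drawn.
#' `"EMw_only"` (ablation mode) uses the median-shortening threshold alone.
#'
#' @param trial a `trial_result` from [run_drug_trial()].
#' @param criterion `"RA_plus_EMw"` (default), `"RA_only"` or `"EMw_only"`.
#' @param multiple which tested concentration multiple to classify at.
#' @param emw_threshold percent threshold (default -10; strict inequality).
#' @param ra_saturation RA fraction above which the drug is risky regardless
#'   of the EMw median (default 0.97).
#' @return object of class `risk_call`: list with `drug`, `criterion`,
#'   `multiple`, `call` ("risky"/"safe") and the evidence used.
#' @export
classify_risk <- function(trial, criterion = c("RA_plus_EMw", "RA_only",
                                               "EMw_only"),
                          multiple = 10, emw_threshold = -10,
                          ra_saturation = 0.97) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(trial, "trial_result"))
  row <- trial$summary[trial$summary$multiple == multiple, ]
  if (nrow(row) != 1)
    stop("trial does not contain concentration multiple ", multiple)
  ra_any <- row$nRA >= 1
  med <- row$median_dEMw
  risky <- switch(criterion,
    RA_only = ra_any,
    RA_plus_EMw = {
      if (row$frac_RA > ra_saturation) TRUE
      else if (is.na(med)) {
        if (ra_any) TRUE
        else stop("degenerate trial: no computable EMw and RA fraction <= ",
                  ra_saturation)
      } else ra_any || (med < emw_threshold)
    },
    EMw_only = {
      if (row$frac_RA > ra_saturation) TRUE
      else if (is.na(med)) stop("degenerate trial: no computable EMw median")
      else med < emw_threshold
    })
  structure(list(drug = trial$drug$name, category = trial$drug$category,
                 criterion = criterion, multiple = multiple,
                 call = if (risky) "risky" else "safe",
                 evidence = list(median_dEMw = med, nRA = row$nRA,
                                 frac_RA = row$frac_RA)),
            class = "risk_call")
}

#' @export
print.risk_call <- function(x, ...) {
  cat(sprintf("<risk_call: %s at %gx -> %s (%s; median dEMw %.2f%%, RA %d)>\n",
              x$drug, x$multiple, toupper(x$call), x$criterion,
              x$evidence$median_dEMw, x$evidence$nRA))
  invisible(x)
}

#' Concentration-weighted TdP score
#'
#' Integrates trial outcomes across tested concentrations into a score in
#' \[0,1\]:
#' \deqn{score = \frac{\sum_i w_i (nRA_i + nEMw_i)}{n_{tot} \sum_i w_i},
#'   \quad w_i = EFTPC_{max}/C_i = 1/multiple_i}
#' where nRA_i counts models with repolarisation abnormalities and nEMw_i
#' counts models with dEMw_i < -10% at concentration i (the two sets are
#' disjoint: RA models have no computable EMw). Setting `n_emw = 0` recovers
#' the original RA-only score. 0 means no model shows RA or above-threshold
#' EMw shortening at any concentration; 1 means every model does at every
#' concentration; events at lower concentrations weigh more.
#'
#' @param n_ra,n_emw integer vectors, one entry per tested concentration.
#' @param multiples concentration multiples of EFTPCmax (define the weights).
#' @param n_tot population size.
#' @return score in \[0,1\].
#' @export
#' @examples
#' tdp_score(n_ra = c(0, 2), n_emw = c(1, 2), multiples = c(1, 10), n_tot = 4)
tdp_score <- function(n_ra, n_emw, multiples, n_tot) {
  k <- length(multiples)
  if (k < 1) stop("at least one concentration is required")
  if (length(n_ra) != k || length(n_emw) != k)
    stop("n_ra and n_emw must have one entry per concentration")
  if (any(n_ra < 0) || any(n_emw < 0) || n_tot < 1)
    stop("counts must be non-negative and n_tot >= 1")
  if (any(n_ra + n_emw > n_tot))
    stop("nRA + nEMw exceeds the population size (double counting?)")
  if (any(multiples <= 0)) stop("concentration multiples must be > 0")
  w <- 1 / multiples
  sum(w * (n_ra + n_emw)) / (n_tot * sum(w))
}

#' TdP score of a finished trial
#'
#' Convenience wrapper evaluating [tdp_score()] on a `trial_result`, under the
#' combined RA + EMw criterion or the original RA-only one.
#'
#' @param trial a `trial_result`.
#' @param include_emw include the EMw-shortening counts (default TRUE).
#' @export
trial_tdp_score <- function(trial, include_emw = TRUE) {
  stopifnot(inherits(trial, "trial_result"))
  s <- trial$summary
  tdp_score(s$nRA, if (include_emw) s$nEMw else rep(0, nrow(s)),
            s$multiple, s$n_tot[1])
}

#' Prediction metrics against the clinical risk categories
#'
#' Maps each drug's clinical TdP category to ground truth (known, possible and
#' conditional risk are positives; NC and unlisted compounds are negatives),
#' crosses it with the in silico calls, and computes the confusion counts and
#' the five standard metrics: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy (TN+TP)/(TN+TP+FN+FP), PPV TP/(TP+FP) and NPV TN/(TN+FN).
#'
#' @param calls list of `risk_call`s (or a data.frame with columns `drug`,
#'   `call`, `category`).
#' @param truth optional named character vector mapping drug names to
#'   categories; defaults to the categories carried by the calls.
#' @return one-row data.frame with TP, TN, FP, FN, sensitivity, specificity,
#'   accuracy, ppv, npv.
#' @export
prediction_metrics <- function(calls, truth = NULL) {
  if (is.data.frame(calls)) df <- calls
  else df <- do.call(rbind, lapply(calls, function(x)
    data.frame(drug = x$drug, call = x$call, category = x$category)))
  if (!is.null(truth)) {
    if (any(!df$drug %in% names(truth)))
      stop("missing truth label for: ",
           paste(setdiff(df$drug, names(truth)), collapse = ", "))
    df$category <- unname(truth[df$drug])
  }
  if (any(is.na(df$category))) stop("missing truth label")
  risky_truth <- df$category %in% c("known", "possible", "conditional")
  risky_call <- df$call == "risky"
  tp <- sum(risky_truth & risky_call)
  tn <- sum(!risky_truth & !risky_call)
  fp <- sum(!risky_truth & risky_call)
  fn <- sum(risky_truth & !risky_call)
  data.frame(TP = tp, TN = tn, FP = fp, FN = fn,
             sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
             accuracy = (tn + tp) / (tn + tp + fn + fp),
             ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Log-modulus transform
#'
#' Sign-preserving logarithmic compression L(x) = sign(x) * log10(|x| + 1),
#' used to display percent EMw changes spanning several orders of magnitude.
#'
#' @param x numeric vector.
#' @export
#' @examples
#' log_modulus(c(-99, 0, 99))   # -2, 0, 2
log_modulus <- function(x) sign(x) * log10(abs(x) + 1)
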