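#' Boxplot of drug-induced EMw changes on a log-modulus axis
#'
#' Per-model percent EMw changes for one or more finished trials at one
#' concentration multiple, displayed with the sign-preserving [log_modulus()]
#' compression and the -10% risk threshold as a dashed line. Mirrors the
#' standard presentation of population dEMw distributions.
#'
#' @param trials a `trial_result` or list of them.
#' @param multiple concentration multiple to display.
#' @param emw_threshold threshold line position (percent).
#' @return a ggplot object.
#' @export
plot_demw <- function(trials, multiple = 10, emw_threshold = -10) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_demw requires the ggplot2 package")
  if (inherits(trials, "trial_result")) trials <- list(trials)
  df <- do.call(rbind, lapply(trials, function(tr) {
    pm <- tr$per_model[tr$per_model$multiple == multiple, ]
    if (!nrow(pm)) return(NULL)
    data.frame(drug = tr$drug$name, category = tr$drug$category,
               dEMw = pm$dEMw)
  }))
  if (is.null(df) || !nrow(df))
    stop("no trial contains concentration multiple ", multiple)
  df <- df[!is.na(df$dEMw), ]
  df$L <- log_modulus(df$dEMw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug, y = .data$L,
                                   fill = .data$category)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = log_modulus(emw_threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL,
                  y = "log-modulus of ΔEMw (%)",
                  title = sprintf("ΔEMw at %gx EFTPCmax", multiple)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
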