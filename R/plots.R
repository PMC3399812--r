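# ggplot2 views of the result objects.

#' Association overview of a called SNP table
#'
#' -log10 chi-square p-value per SNP along the alignment, highlighting the
#' screen threshold.
#'
#' @param object A `snp_table` with association columns (see [snp_assoc()]).
#' @param alpha Screen level drawn as a dashed reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot snp_table
#' @export
autoplot.snp_table <- function(object, alpha = 0.05, ...) {
  if (!"p" %in% names(object)) object <- snp_assoc(object)
  df <- dplyr::mutate(object,
                      label = paste0("SNP", .data$snp_no),
                      significant = .data$p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "alignment column", y = expression(-log[10](italic(p))),
                  title = "Per-SNP case-control chi-square screen") +
    ggplot2::theme_minimal()
}

#' Forest plot of a logistic fit
#'
#' Odds ratios with 95% Wald intervals per model term (intercept omitted),
#' on a log scale.
#'
#' @param object A `dloop_logit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dloop_logit
#' @export
autoplot.dloop_logit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$or, y = stats::reorder(.data$term, .data$or))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Recovery-experiment summary plot
#'
#' Recovered versus planted case allele frequency per site, with the identity
#' line.
#'
#' @param object A `recovery_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_summary
#' @export
autoplot.recovery_summary <- function(object, ...) {
  ggplot2::ggplot(object$sites,
                  ggplot2::aes(x = .data$case_freq, y = .data$mean_case_freq_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "planted case allele frequency",
                  y = "mean recovered case allele frequency",
                  title = "Allele-frequency recovery across replicates") +
    ggplot2::theme_minimal()
}
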