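# ggplot2 views of the pipeline's result objects.

#' Plot microarray-vs-qPCR concordance
#'
#' Scatter of qPCR against microarray expression changes with the
#' least-squares line and the Pearson R in the subtitle — the standard
#' cross-platform validation figure.
#'
#' @param object An `mf_concordance`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mf_concordance
#' @export
autoplot.mf_concordance <- function(object, ...) {
  lab <- if (object$scale == "fold") "signed fold change" else "log2 ratio"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$array_value, y = .data$qpcr_value)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste("microarray", lab), y = paste("qPCR", lab),
      title = "Microarray vs qPCR concordance",
      subtitle = sprintf("Pearson R = %.2f (n = %d)", object$r, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot top over-represented terms
#'
#' Horizontal bars of -log10 BH-adjusted p for the most significant terms.
#'
#' @param object An `mf_enrichment` tibble.
#' @param top Number of terms shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mf_enrichment
#' @export
autoplot.mf_enrichment <- function(object, top = 10, ...) {
  d <- head(tibble::as_tibble(object), top)
  d$term <- factor(paste(d$term_id, d$term_label),
                   levels = rev(paste(d$term_id, d$term_label)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$adjusted_p),
                                  y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ "BH-adjusted p"), y = NULL,
                  title = "Term over-representation") +
    ggplot2::theme_minimal()
}

#' Plot the fold-change landscape of a run
#'
#' Histogram of per-gene log2 ratios faceted by phase, with the DE
#' thresholds marked.
#'
#' @param object An `mf_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mf_run
#' @export
autoplot.mf_run <- function(object, ...) {
  thr <- log2(object$params$threshold)
  ggplot2::ggplot(object$fold_changes,
                  ggplot2::aes(x = .data$log2_ratio)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "log2 expression ratio (treatment / control)",
                  y = "genes",
                  title = "Expression ratios with DE thresholds") +
    ggplot2::theme_minimal()
}
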