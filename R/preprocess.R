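# Cross-array scale-factor normalization and replicate trimmed-mean
# summarization. The normalization puts each treatment array on its
# phase-matched control array's intensity scale via a single multiplicative
# factor SF = mu_control / mu_treatment computed from array-wide mean median
# spot signals; summarization then discards one maximum and one minimum
# adjusted signal per replicate group and averages the rest.

#' Mean median-spot signal of one array
#'
#' @param probes Probe-level tibble.
#' @param array_id Array identifier.
#' @param exclude_genes Optional gene ids (e.g. control oligos) excluded
#'   from the mean.
#' @return The arithmetic mean of the array's spot signals.
#' @export
array_mean_signal <- function(probes, array_id, exclude_genes = NULL) {
  sel <- probes$array_id == array_id
  if (!any(sel)) abort(paste0("unknown array id: ", array_id))
  if (!is.null(exclude_genes)) sel <- sel & !(probes$gene_id %in% exclude_genes)
  if (!any(sel)) abort(paste0("no spots left on array ", array_id,
                              " after exclusions"))
  mean(probes$signal[sel])
}

#' Compute the cross-array scale factor
#'
#' The scale factor is the ratio of the control array's mean median spot
#' signal to the treatment array's: `SF = mu_control / mu_treatment`.
#' Multiplying the treatment array by SF equalizes the two array means,
#' compensating for array-to-array differences in overall intensity.
#'
#' @inheritParams array_mean_signal
#' @param control_array,treatment_array Array identifiers of the contrast.
#' @return An object of class `mf_scale_factor`: list with `value`,
#'   `control_mean`, `treatment_mean`.
#' @examples
#' p <- tibble::tibble(gene_id = "g", probe_index = 1:2,
#'                     array_id = rep(c("c", "t"), each = 2),
#'                     condition = rep(c("control", "treatment"), each = 2),
#'                     phase = "x", signal = c(900, 1100, 400, 600))
#' compute_scale_factor(p, "c", "t")$value  # 1000 / 500 = 2
#' @export
compute_scale_factor <- function(probes, control_array, treatment_array,
                                 exclude_genes = NULL) {
  mu_c <- array_mean_signal(probes, control_array, exclude_genes)
  mu_t <- array_mean_signal(probes, treatment_array, exclude_genes)
  if (!is.finite(mu_t) || mu_t <= 0) {
    abort(paste0("degenerate input: treatment array ", treatment_array,
                 " has mean signal ", mu_t, " (must be > 0)"))
  }
  structure(list(value = mu_c / mu_t, control_mean = mu_c,
                 treatment_mean = mu_t,
                 control_array = control_array,
                 treatment_array = treatment_array),
            class = "mf_scale_factor")
}

#' @export
print.mf_scale_factor <- function(x, ...) {
  cat(sprintf("<scale factor> SF = %.6g (mu_control %.6g / mu_treatment %.6g)\n",
              x$value, x$control_mean, x$treatment_mean))
  invisible(x)
}

#' Apply a scale factor to a treatment array
#'
#' Multiplies every spot signal on `treatment_array` by the scale factor;
#' all other spots are untouched. Afterwards the adjusted treatment array
#' mean equals the control array mean to within floating-point tolerance.
#'
#' @inheritParams compute_scale_factor
#' @param sf An `mf_scale_factor` or a single positive number.
#' @return The probe tibble with adjusted treatment signals.
#' @export
apply_scale_factor <- function(probes, treatment_array, sf) {
  value <- if (inherits(sf, "mf_scale_factor")) sf$value else sf
  check_positive_scalar(value, "sf")
  if (!any(probes$array_id == treatment_array)) {
    abort(paste0("unknown array id: ", treatment_array))
  }
  dplyr::mutate(probes, signal = ifelse(.data$array_id == treatment_array,
                                        .data$signal * value, .data$signal))
}

#' Trimmed-mean summarization of replicate probe spots
#'
#' Summarizes each (gene, array) replicate group of adjusted signals into a
#' single gene-level signal: with four or more replicates, exactly one
#' occurrence of the maximum and one of the minimum are discarded (ties
#' still lose exactly one value per extreme) and the remaining values are
#' averaged; with exactly three, all three are averaged. Groups with fewer
#' than three values are flagged unsummarizable and excluded with a warning.
#' Run this after [apply_scale_factor()] so the trimming sees adjusted
#' signals.
#'
#' @param probes Probe-level tibble of adjusted signals.
#' @return A gene-level tibble with columns `gene_id`, `array_id`,
#'   `condition`, `phase`, `signal`, `n_used`, `n_discarded`.
#' @examples
#' p <- tibble::tibble(gene_id = "g", probe_index = 1:5, array_id = "a",
#'                     condition = "control", phase = "x",
#'                     signal = c(10, 2, 8, 100, 6))
#' trimmed_mean_summarize(p)$signal  # (10 + 8 + 6) / 3 = 8
#' @export
trimmed_mean_summarize <- function(probes) {
  counts <- dplyr::count(probes, .data$gene_id, .data$array_id,
                         .data$condition, .data$phase, name = "n_total")
  short <- unique(counts$gene_id[counts$n_total < 3])
  if (length(short) > 0) {
    warn(paste0(length(short), " gene(s) unsummarizable (< 3 replicates) ",
                "and excluded: ", paste(head(short, 5), collapse = ", ")))
    probes <- probes[!(probes$gene_id %in% short), ]
    counts <- counts[!(counts$gene_id %in% short), ]
  }
  # Sort within group and drop the first (one minimum) and last (one
  # maximum) value whenever >= 4 replicates survive; mean over the rest in
  # ascending order, matching the sort-then-average-middle definition
  # exactly (same summation order).
  g <- dplyr::group_by(probes, .data$gene_id, .data$array_id,
                       .data$condition, .data$phase)
  g <- dplyr::arrange(g, .data$signal, .by_group = TRUE)
  kept <- dplyr::filter(g, dplyr::n() < 4 |
                          (dplyr::row_number() > 1 &
                             dplyr::row_number() < dplyr::n()))
  out <- dplyr::summarise(kept, signal = mean(.data$signal),
                          n_used = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(out, counts,
                          by = c("gene_id", "array_id", "condition", "phase"))
  out$n_discarded <- out$n_total - out$n_used
  out$n_total <- NULL
  dplyr::arrange(out, .data$array_id, .data$gene_id)
}
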