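# Comparative-CT (2^-ddCT) relative quantification with a reference-gene
# stability check, and microarray-vs-qPCR concordance. Amplification
# efficiency is fixed at 2 per cycle, the comparative-CT assumption.

#' Reference-gene stability across conditions
#'
#' A valid comparative-CT reference must amplify at a constant CT in every
#' condition. Reports the per-condition mean reference CT, the maximum
#' absolute between-condition difference, and a pass/fail against a
#' tolerance in cycles.
#'
#' @param ct CT tibble (`condition`, `gene_id`, `well`, `ct`).
#' @param reference_gene Reference gene id (e.g. 16S rRNA).
#' @param tolerance Maximum acceptable between-condition mean CT difference,
#'   in cycles.
#' @return List of class `mf_ref_stability`: `per_condition` tibble,
#'   `max_diff`, `tolerance`, `pass`.
#' @export
reference_stability <- function(ct, reference_gene, tolerance = 0.5) {
  ref <- ct[ct$gene_id == reference_gene, ]
  conds <- unique(ct$condition)
  missing <- setdiff(conds, unique(ref$condition))
  if (nrow(ref) == 0 || length(missing) > 0) {
    abort(paste0("reference gene '", reference_gene,
                 "' missing in condition(s): ",
                 paste(if (nrow(ref) == 0) conds else missing,
                       collapse = ", ")))
  }
  per_condition <- dplyr::summarise(dplyr::group_by(ref, .data$condition),
                                    mean_ct = mean(.data$ct),
                                    n_wells = dplyr::n(), .groups = "drop")
  if (nrow(per_condition) == 1) {
    warn("single condition: reference stability is trivially satisfied")
  }
  max_diff <- if (nrow(per_condition) > 1) {
    max(per_condition$mean_ct) - min(per_condition$mean_ct)
  } else 0
  structure(list(per_condition = per_condition, max_diff = max_diff,
                 tolerance = tolerance, pass = max_diff <= tolerance,
                 reference_gene = reference_gene),
            class = "mf_ref_stability")
}

#' @export
print.mf_ref_stability <- function(x, ...) {
  cat(sprintf("<reference stability> %s: max |delta CT| = %.3f cycles (%s at tolerance %.2f)\n",
              x$reference_gene, x$max_diff,
              if (x$pass) "PASS" else "FAIL", x$tolerance))
  invisible(x)
}

#' Comparative-CT relative expression (2^-ddCT)
#'
#' For each target gene, well-replicate CTs are averaged per condition, the
#' reference gene's mean CT is subtracted (dCT), the control condition's dCT
#' is subtracted from the treatment's (ddCT), and relative expression is
#' `2^-ddCT`. A signed qPCR fold change is attached using the same
#' convention as the array pipeline ([signed_fold_change()]).
#'
#' @param ct CT tibble (`condition`, `gene_id`, `well`, `ct`), one phase.
#' @param reference_gene Reference gene id.
#' @param control_label,treatment_label Condition labels.
#' @return Tibble with `gene_id`, `delta_ct_control`, `delta_ct_treatment`,
#'   `delta_delta_ct`, `relative_expression`, `qpcr_fold_change`. Genes
#'   absent in one condition are skipped with a warning.
#' @examples
#' ct <- tibble::tibble(
#'   condition = rep(c("treatment", "control"), each = 2),
#'   gene_id = rep(c("tgt", "ref"), 2), well = 1L,
#'   ct = c(20, 10, 24, 10))
#' delta_delta_ct(ct, "ref")  # ddCT = -4, relative expression 16
#' @export
delta_delta_ct <- function(ct, reference_gene, control_label = "control",
                           treatment_label = "treatment") {
  for (lab in c(control_label, treatment_label)) {
    if (!any(ct$condition == lab)) {
      abort(paste0("condition '", lab, "' not present in the CT table"))
    }
  }
  means <- dplyr::summarise(dplyr::group_by(ct, .data$condition, .data$gene_id),
                            mean_ct = mean(.data$ct), .groups = "drop")
  ref <- means[means$gene_id == reference_gene, ]
  for (lab in c(control_label, treatment_label)) {
    if (!any(ref$condition == lab)) {
      abort(paste0("reference gene '", reference_gene,
                   "' missing in condition '", lab, "'"))
    }
  }
  ref_ct <- setNames(ref$mean_ct, ref$condition)
  targets <- means[means$gene_id != reference_gene, ]
  wide <- tidyr::pivot_wider(targets, names_from = "condition",
                             values_from = "mean_ct")
  have_both <- !is.na(wide[[control_label]]) & !is.na(wide[[treatment_label]])
  if (any(!have_both)) {
    warn(paste0(sum(!have_both), " gene(s) measured in only one condition ",
                "skipped: ",
                paste(head(wide$gene_id[!have_both], 5), collapse = ", ")))
    wide <- wide[have_both, ]
  }
  d_ctl <- wide[[control_label]] - ref_ct[[control_label]]
  d_trt <- wide[[treatment_label]] - ref_ct[[treatment_label]]
  ddct <- d_trt - d_ctl
  tibble::tibble(
    gene_id = wide$gene_id,
    delta_ct_control = d_ctl,
    delta_ct_treatment = d_trt,
    delta_delta_ct = ddct,
    relative_expression = 2^(-ddct),
    qpcr_fold_change = signed_fold_change(2^(-ddct))
  )
}

#' Microarray-vs-qPCR concordance
#'
#' Pearson correlation between platform-matched expression changes for the
#' genes shared by a fold-change record table and a comparative-CT result
#' table, plus the least-squares line. `scale = "fold"` correlates signed
#' fold changes (the scale of a typical validation scatter plot);
#' `scale = "log2"` correlates log2 ratios with -ddCT.
#'
#' @param array_records Fold-change tibble ([fold_change_table()]).
#' @param qpcr_records Tibble from [delta_delta_ct()].
#' @param scale `"fold"` or `"log2"`.
#' @return List of class `mf_concordance`: `r`, `n`, `slope`, `intercept`,
#'   `scale`, and the joined `data` tibble (`gene_id`, `array_value`,
#'   `qpcr_value`).
#' @export
concordance <- function(array_records, qpcr_records,
                        scale = c("fold", "log2")) {
  scale <- match.arg(scale)
  joined <- dplyr::inner_join(
    dplyr::select(array_records, "gene_id", "fold_change", "log2_ratio"),
    dplyr::select(qpcr_records, "gene_id", "qpcr_fold_change",
                  "delta_delta_ct"),
    by = "gene_id")
  if (nrow(joined) < 3) {
    abort(paste0("concordance needs >= 3 shared genes; found ", nrow(joined)))
  }
  data <- if (scale == "fold") {
    tibble::tibble(gene_id = joined$gene_id,
                   array_value = joined$fold_change,
                   qpcr_value = joined$qpcr_fold_change)
  } else {
    tibble::tibble(gene_id = joined$gene_id,
                   array_value = joined$log2_ratio,
                   qpcr_value = -joined$delta_delta_ct)
  }
  if (stats::var(data$array_value) == 0 || stats::var(data$qpcr_value) == 0) {
    abort("zero variance in one platform's values; correlation undefined")
  }
  fit <- lm(qpcr_value ~ array_value, data = data)
  structure(list(r = cor(data$array_value, data$qpcr_value),
                 n = nrow(data),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 scale = scale, data = data),
            class = "mf_concordance")
}

#' @export
print.mf_concordance <- function(x, ...) {
  cat(sprintf("<concordance> R = %.3f over %d genes (%s scale); fit: qPCR = %.3f x array %+.3f\n",
              x$r, x$n, x$scale, x$slope, x$intercept))
  invisible(x)
}
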