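# Expression ratios, the signed fold-change convention, log2 ratios and
# threshold-based differential-expression calls. With one pooled array per
# condition there is no within-contrast variance estimate, so DE calling is
# threshold-only by design.

#' Per-gene expression ratios between two summarized arrays
#'
#' Divides each gene's treatment-array summarized signal by its control-array
#' summarized signal. Genes whose control signal does not exceed `floor` get
#' no defined ratio and are excluded with a warning; treatment signals at or
#' below `floor` are computed against the floor and flagged.
#'
#' @param gene_signals Gene-level tibble from [trimmed_mean_summarize()].
#' @param control_array,treatment_array Array identifiers.
#' @param floor Positive signal floor below which a summary is considered
#'   indistinguishable from background.
#' @return Tibble with `gene_id`, `control_signal`, `treatment_signal`,
#'   `ratio`, `flag` (`"ok"`, `"treatment_floor"`).
#' @export
expression_ratio <- function(gene_signals, control_array, treatment_array,
                             floor = 1) {
  check_positive_scalar(floor, "floor")
  ctl <- gene_signals[gene_signals$array_id == control_array, ]
  trt <- gene_signals[gene_signals$array_id == treatment_array, ]
  if (nrow(ctl) == 0) abort(paste0("unknown array id: ", control_array))
  if (nrow(trt) == 0) abort(paste0("unknown array id: ", treatment_array))
  both <- dplyr::inner_join(
    dplyr::select(ctl, "gene_id", control_signal = "signal"),
    dplyr::select(trt, "gene_id", treatment_signal = "signal"),
    by = "gene_id")
  undef <- both$control_signal <= floor
  if (any(undef)) {
    warn(paste0(sum(undef), " gene(s) with control signal at/below the ",
                "floor (", floor, ") have no defined ratio and are excluded"))
    both <- both[!undef, ]
  }
  if (nrow(both) == 0) abort("no gene has a defined expression ratio")
  trt_floor <- both$treatment_signal <= floor
  dplyr::mutate(both,
                ratio = pmax(.data$treatment_signal, floor) / .data$control_signal,
                flag = ifelse(trt_floor, "treatment_floor", "ok"))
}

#' Signed fold change from an expression ratio
#'
#' Ratios of at least one are reported unchanged; ratios below one are
#' reported as the negated reciprocal, so a halving reads as -2-fold and the
#' result never falls in the open interval (-1, 1).
#'
#' @param ratio Positive numeric vector of treatment/control ratios.
#' @return Signed fold changes with `|fold| >= 1`.
#' @examples
#' signed_fold_change(c(0.5, 1, 3.2))  # -2, 1, 3.2
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    abort("expression ratios must be finite and > 0")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Log2 of an expression ratio
#'
#' @param ratio Positive numeric vector.
#' @return `log2(ratio)`.
#' @export
log2_ratio <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    abort("expression ratios must be finite and > 0")
  }
  log2(ratio)
}

#' Build the per-gene fold-change record table
#'
#' Combines [expression_ratio()] output with the signed fold-change and log2
#' transforms and a threshold DE call per gene.
#'
#' @param ratios Output of [expression_ratio()].
#' @param phase Phase label attached to every record.
#' @param threshold Fold-change call threshold (>= 1).
#' @param strict Use strict `>` comparison (default); `FALSE` uses `>=`.
#' @return Tibble with `gene_id`, `phase`, `ratio`, `fold_change`,
#'   `log2_ratio`, `de_call` (`"up"`, `"down"`, `"none"`), `flag`.
#' @export
fold_change_table <- function(ratios, phase = NA_character_, threshold = 3,
                              strict = TRUE) {
  if (threshold < 1) abort("'threshold' must be >= 1")
  fc <- signed_fold_change(ratios$ratio)
  up <- if (strict) fc > threshold else fc >= threshold
  down <- if (strict) fc < -threshold else fc <= -threshold
  tibble::tibble(
    gene_id = ratios$gene_id,
    phase = phase,
    ratio = ratios$ratio,
    fold_change = fc,
    log2_ratio = log2_ratio(ratios$ratio),
    de_call = dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ "none"),
    flag = ratios$flag %||% "ok"
  )
}

#' Call differentially expressed genes at a fold-change threshold
#'
#' Splits fold-change records into up- and down-regulated lists at a signed
#' fold-change threshold, each sorted by absolute fold change descending
#' with ties broken by gene id.
#'
#' @param records Fold-change tibble (from [fold_change_table()], or any
#'   tibble with `gene_id` and `fold_change`).
#' @param threshold Fold-change threshold (>= 1; default 3, i.e. "more than
#'   3-fold").
#' @param strict Strict `>` comparison (default) or inclusive `>=`.
#' @return An object of class `mf_de_calls`: list with tibbles `up` and
#'   `down`, the full `records` with a `de_call` column, and the calling
#'   parameters.
#' @examples
#' rec <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
#'                       fold_change = c(3.5, -4, 2.9, -3))
#' call_differential(rec, threshold = 3)$up$gene_id
#' @export
call_differential <- function(records, threshold = 3, strict = TRUE) {
  if (threshold < 1) abort("'threshold' must be >= 1")
  fc <- records$fold_change
  up_sel <- if (strict) fc > threshold else fc >= threshold
  down_sel <- if (strict) fc < -threshold else fc <= -threshold
  records$de_call <- dplyr::case_when(up_sel ~ "up", down_sel ~ "down",
                                      TRUE ~ "none")
  ord <- function(d) d[order(-abs(d$fold_change), d$gene_id), ]
  structure(
    list(up = ord(records[up_sel, , drop = FALSE]),
         down = ord(records[down_sel, , drop = FALSE]),
         records = records, threshold = threshold, strict = strict),
    class = "mf_de_calls"
  )
}

#' @export
print.mf_de_calls <- function(x, ...) {
  cmp <- if (x$strict) ">" else ">="
  cat("<DE calls> |fold| ", cmp, " ", x$threshold, ": ",
      nrow(x$up), " up, ", nrow(x$down), " down, ",
      nrow(x$records) - nrow(x$up) - nrow(x$down), " unchanged\n", sep = "")
  invisible(x)
}
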