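# Internal validation helpers shared across modules.

probe_table_cols <- c("gene_id", "probe_index", "array_id", "condition",
                      "phase", "signal")

#' Validate a probe-level signal table
#'
#' Checks the structural invariants of a spot-level table: required columns,
#' non-negative finite signals, every gene present on every array, and a
#' constant replicate count per (gene, array) group when a design replicate
#' count is supplied.
#'
#' @param probes A data frame of spot-level signals with columns `gene_id`,
#'   `probe_index`, `array_id`, `condition`, `phase`, `signal`.
#' @param n_probe_reps Optional design replicate count; when given, every
#'   (gene, array) group must contain exactly this many rows.
#' @return `probes`, invisibly, as a tibble. Errors on violation.
#' @export
validate_probe_table <- function(probes, n_probe_reps = NULL) {
  probes <- tibble::as_tibble(probes)
  missing <- setdiff(probe_table_cols, names(probes))
  if (length(missing) > 0) {
    abort(paste0("probe table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.numeric(probes$signal)) {
    abort("probe table column 'signal' must be numeric")
  }
  if (any(!is.finite(probes$signal))) {
    abort("probe table contains non-finite signals")
  }
  if (any(probes$signal < 0)) {
    abort("probe table contains negative signals; spot medians must be >= 0")
  }
  counts <- dplyr::count(probes, .data$gene_id, .data$array_id)
  n_arrays <- dplyr::n_distinct(probes$array_id)
  per_gene <- dplyr::count(counts, .data$gene_id)
  if (any(per_gene$n != n_arrays)) {
    bad <- per_gene$gene_id[per_gene$n != n_arrays]
    abort(paste0("gene(s) absent from some arrays: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.null(n_probe_reps) && any(counts$n != n_probe_reps)) {
    bad <- unique(counts$gene_id[counts$n != n_probe_reps])
    abort(paste0("replicate count differs from design (", n_probe_reps,
                 ") for gene(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  invisible(probes)
}

# Positive-scalar check with a readable message.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("'", name, "' must be a single finite positive number"))
  }
  invisible(x)
}

# Recycle a per-phase parameter (length 1 or n_phases) to length n_phases.
recycle_phase <- function(x, n_phases, name) {
  if (length(x) == 1) x <- rep(x, n_phases)
  if (length(x) != n_phases) {
    abort(paste0("'", name, "' must have length 1 or n_phases (", n_phases, ")"))
  }
  x
}
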