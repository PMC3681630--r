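# Readers and writers for the pipeline's tabular formats. TSV is the primary
# interchange format; a minimal GenePix-style (GPR) dialect reads single-array
# spot files by named id/median-signal columns so deposited arrays can be fed
# in after export. All writers round-trip through the matching reader.

#' Read a probe-level signal table
#'
#' Reads spot-level median intensities either from the pipeline's native TSV
#' schema (`gene_id`, `probe_index`, `array_id`, `condition`, `phase`,
#' `signal`) or from a GenePix-style tab-delimited spot file (`dialect =
#' "gpr"`): an optional ATF preamble, a header row, one row per physical
#' spot. In the GPR dialect the gene identity comes from `id_col`, the
#' signal from `signal_col`, and replicate indices are assigned to repeated
#' ids in order of appearance.
#'
#' Genes with fewer than `min_reps` spots on an array are rejected with a
#' warning (the trimmed mean needs at least three values); genes whose
#' replicate count differs from `n_probe_reps` (when given) are reported.
#' Non-numeric signals are a hard format error naming the offending line.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (native schema) or `"gpr"` (named-column subset of
#'   a GenePix results file).
#' @param id_col,signal_col Column names holding the gene id and the median
#'   spot signal in the GPR dialect.
#' @param array_id,condition,phase Metadata attached to every spot when the
#'   file itself carries none (GPR files describe a single array). Defaults:
#'   the file name, `NA`, `NA`.
#' @param min_reps Minimum spots per (gene, array) for a gene to be kept.
#' @param n_probe_reps Optional design replicate count used for reporting.
#' @return A validated probe-level tibble.
#' @export
read_probe_table <- function(path, dialect = c("tsv", "gpr"),
                             id_col = "ID", signal_col = "F532 Median",
                             array_id = NULL, condition = NA_character_,
                             phase = NA_character_, min_reps = 3,
                             n_probe_reps = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing <- setdiff(probe_table_cols, names(raw))
    if (length(missing) > 0) {
      abort(paste0("format error in ", path, ": missing column(s) ",
                   paste(missing, collapse = ", ")))
    }
    sig <- parse_signal(raw$signal, path, line_offset = 1L)
    probes <- tibble::tibble(
      gene_id = raw$gene_id,
      probe_index = as.integer(raw$probe_index),
      array_id = raw$array_id,
      condition = raw$condition,
      phase = raw$phase,
      signal = sig
    )
  } else {
    skip <- gpr_header_skip(path)
    raw <- readr::read_tsv(path, skip = skip,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing <- setdiff(c(id_col, signal_col), names(raw))
    if (length(missing) > 0) {
      abort(paste0("format error in ", path, ": missing column(s) ",
                   paste(missing, collapse = ", ")))
    }
    sig <- parse_signal(raw[[signal_col]], path, line_offset = skip + 1L)
    probes <- tibble::tibble(
      gene_id = raw[[id_col]],
      array_id = array_id %||% basename(path),
      condition = condition,
      phase = phase,
      signal = sig
    )
    # replicate index of repeated ids by order of appearance in the file
    probes <- dplyr::mutate(
      dplyr::group_by(probes, .data$gene_id),
      probe_index = dplyr::row_number()
    )
    probes <- dplyr::ungroup(probes)
    probes <- probes[, probe_table_cols]
  }
  if (any(probes$signal < 0)) {
    abort(paste0("format error in ", path,
                 ": negative signal(s); spot medians must be >= 0"))
  }
  enforce_replicate_rules(probes, min_reps = min_reps,
                          n_probe_reps = n_probe_reps)
}

# Signals arrive as character; reject non-numeric values loudly with the
# 1-based file line number (header and any preamble included).
parse_signal <- function(x, path, line_offset) {
  sig <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(sig) & !(is.na(x) | x %in% c("NA", "")))
  if (length(bad) > 0) {
    abort(paste0("format error in ", path, ": non-numeric signal '",
                 x[bad[1]], "' at line ", bad[1] + line_offset))
  }
  if (any(is.na(sig))) {
    abort(paste0("format error in ", path, ": missing signal value(s)"))
  }
  sig
}

# Number of lines to skip before the column-header row of a GPR-like file:
# ATF files open with "ATF <version>" then "<n_headers> <n_columns>".
gpr_header_skip <- function(path) {
  first <- readLines(path, n = 2L)
  if (length(first) >= 1 && grepl("^ATF", first[1])) {
    n_head <- suppressWarnings(as.integer(strsplit(trimws(first[2]),
                                                   "\\s+")[[1]][1]))
    if (is.na(n_head)) {
      abort(paste0("format error in ", path, ": malformed ATF preamble"))
    }
    2L + n_head
  } else {
    0L
  }
}

# Drop genes with too few spots per array (warn), report count mismatches
# against the design, and validate the result.
enforce_replicate_rules <- function(probes, min_reps, n_probe_reps = NULL) {
  counts <- dplyr::count(probes, .data$gene_id, .data$array_id)
  short <- unique(counts$gene_id[counts$n < min_reps])
  if (length(short) > 0) {
    warn(paste0(length(short), " gene(s) with fewer than ", min_reps,
                " replicate spots excluded: ",
                paste(head(short, 5), collapse = ", ")))
    probes <- probes[!(probes$gene_id %in% short), ]
    counts <- counts[!(counts$gene_id %in% short), ]
  }
  if (!is.null(n_probe_reps)) {
    off <- unique(counts$gene_id[counts$n != n_probe_reps])
    if (length(off) > 0) {
      warn(paste0(length(off), " gene(s) with a replicate count different ",
                  "from the design (", n_probe_reps, "): ",
                  paste(head(off, 5), collapse = ", ")))
    }
  }
  if (nrow(probes) == 0) abort("no genes left after replicate filtering")
  validate_probe_table(probes)
  tibble::as_tibble(probes)
}

#' Write a probe-level signal table as TSV
#'
#' Writes the native schema with full (round-trip exact) double precision.
#' `read_probe_table(write_probe_table(x, p))` returns a table equal to `x`.
#'
#' @param probes Probe-level tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  probes <- validate_probe_table(probes)
  readr::write_tsv(probes[, probe_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Read or write a gene-to-term annotation table
#'
#' Long-format TSV with columns `term_id`, `term_label`, `gene_id`.
#'
#' @param path File path.
#' @return A tibble (reader) or `path` invisibly (writer).
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  missing <- setdiff(c("term_id", "term_label", "gene_id"), names(ann))
  if (length(missing) > 0) {
    abort(paste0("format error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  ann
}

#' @rdname read_annotation
#' @param annotation Annotation tibble to write.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[, c("term_id", "term_label", "gene_id")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read or write a qPCR CT table
#'
#' TSV with columns `phase` (optional on read), `condition`, `gene_id`,
#' `well`, `ct`.
#'
#' @param path File path.
#' @return A tibble (reader) or `path` invisibly (writer).
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_tsv(path, col_types = readr::cols(
    well = readr::col_integer(), ct = readr::col_double(),
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(c("condition", "gene_id", "well", "ct"), names(ct))
  if (length(missing) > 0) {
    abort(paste0("format error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort(paste0("format error in ", path, ": CT values must be finite and > 0"))
  }
  ct
}

#' @rdname read_ct_table
#' @param ct CT tibble to write.
#' @export
write_ct_table <- function(ct, path) {
  cols <- intersect(c("phase", "condition", "gene_id", "well", "ct"), names(ct))
  readr::write_tsv(ct[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write fold-change results with fixed formatting
#'
#' Writes per-gene fold-change records as TSV with deterministic column
#' order (`gene_id`, `phase`, `ratio`, `fold_change`, `log2_ratio`,
#' `de_call`) and all numeric columns formatted to six decimal places, so
#' repeated writes of the same records are byte-identical.
#'
#' @param records Fold-change tibble (see [fold_change_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  cols <- c("gene_id", "phase", "ratio", "fold_change", "log2_ratio", "de_call")
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    abort(paste0("results are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    gene_id = as.character(records$gene_id),
    phase = as.character(records$phase),
    ratio = sprintf("%.6f", records$ratio),
    fold_change = sprintf("%.6f", records$fold_change),
    log2_ratio = sprintf("%.6f", records$log2_ratio),
    de_call = as.character(records$de_call)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  res <- readr::read_tsv(path, col_types = readr::cols(
    ratio = readr::col_double(), fold_change = readr::col_double(),
    log2_ratio = readr::col_double(), .default = readr::col_character()),
    progress = FALSE)
  missing <- setdiff(c("gene_id", "phase", "ratio", "fold_change",
                       "log2_ratio", "de_call"), names(res))
  if (length(missing) > 0) {
    abort(paste0("format error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  res
}
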