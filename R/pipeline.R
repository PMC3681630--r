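# End-to-end orchestration: simulate (or accept user tables) -> scale ->
# trim -> ratio -> fold -> DE -> enrichment -> qPCR/concordance, with all
# intermediate tables and a machine-readable run summary written when an
# output directory is given.

#' Run the full expression-analysis pipeline
#'
#' Executes every stage in fixed order for each phase contrast:
#' scale-factor normalization of the treatment array against its
#' phase-matched control, trimmed-mean summarization, expression ratios,
#' signed fold changes, threshold DE calls, term over-representation of the
#' DE list, and — when CT data are present — comparative-CT quantification
#' with a reference-stability check and microarray-vs-qPCR concordance.
#'
#' By default the input is simulated from `config`, so the run carries
#' ground truth; supplying `probes` (plus optional `annotation` and `ct`)
#' runs the same pipeline on user data. The probe table must hold exactly
#' one control and one treatment array per phase (the pooled-sample design).
#'
#' @param config An [sim_config()]; also supplies the signal floor and
#'   reference gene id.
#' @param probes Optional probe-level tibble (skips simulation).
#' @param annotation Optional annotation tibble; `NULL` disables enrichment.
#' @param ct Optional CT tibble; `NULL` disables the qPCR branch.
#' @param threshold,strict DE calling parameters (see [call_differential()]).
#' @param method Enrichment statistic, `"fisher"` or `"ease"`.
#' @param scale Concordance scale, `"fold"` or `"log2"`.
#' @param alpha BH-adjusted significance threshold for counting enriched
#'   terms in the summary.
#' @param background `"defined"` restricts the enrichment universe to genes
#'   with a defined expression ratio (genes excluded by QC cannot be called
#'   DE); `"all"` uses every gene on the array.
#' @param outdir Optional directory; when given, all stage outputs, the
#'   summary JSON and a text report are written deterministically.
#' @return An object of class `mf_run`: list with `fold_changes` (all
#'   phases), per-phase `de`, `enrichment`, `qpcr`, `ref_stability`,
#'   `concordance` and `scale_factors` lists, the `summary` tibble,
#'   `experiment` (when simulated), and the run parameters.
#' @examples
#' run <- run_pipeline(sim_config(n_genes = 80, seed = 3))
#' run$summary
#' @export
run_pipeline <- function(config = sim_config(), probes = NULL,
                         annotation = NULL, ct = NULL,
                         threshold = 3, strict = TRUE,
                         method = c("fisher", "ease"),
                         scale = c("fold", "log2"),
                         alpha = 0.05, background = c("defined", "all"),
                         outdir = NULL) {
  stopifnot(inherits(config, "mf_config"))
  method <- match.arg(method)
  scale <- match.arg(scale)
  background <- match.arg(background)

  experiment <- NULL
  if (is.null(probes)) {
    experiment <- simulate_experiment(config)
    probes <- experiment$probes
    annotation <- annotation %||% experiment$annotation
    ct <- ct %||% experiment$ct
  } else {
    probes <- validate_probe_table(probes)
  }

  phases <- unique(probes$phase)
  per_phase <- purrr::map(phases, function(ph) {
    pp <- probes[probes$phase == ph, ]
    ids <- dplyr::distinct(pp, .data$array_id, .data$condition)
    ctl <- ids$array_id[ids$condition == "control"]
    trt <- ids$array_id[ids$condition == "treatment"]
    if (length(ctl) != 1 || length(trt) != 1) {
      abort(paste0("preprocess stage: phase '", ph, "' must have exactly ",
                   "one control and one treatment array"))
    }
    sf <- compute_scale_factor(pp, ctl, trt)
    adj <- apply_scale_factor(pp, trt, sf)
    gs <- trimmed_mean_summarize(adj)
    ratios <- expression_ratio(gs, ctl, trt, floor = config$signal_floor)
    fc <- fold_change_table(ratios, phase = ph, threshold = threshold,
                            strict = strict)
    de <- call_differential(fc, threshold = threshold, strict = strict)

    enr <- NULL
    if (!is.null(annotation)) {
      universe <- if (background == "defined") fc$gene_id else
        unique(pp$gene_id)
      de_ids <- c(de$up$gene_id, de$down$gene_id)
      enr <- term_enrichment(de_ids, universe, annotation, method = method)
    }

    qp <- NULL; ref <- NULL; conc <- NULL
    if (!is.null(ct) && "phase" %in% names(ct) && any(ct$phase == ph)) {
      ct_p <- ct[ct$phase == ph, ]
      ref <- reference_stability(ct_p, config$reference_gene)
      qp <- delta_delta_ct(ct_p, config$reference_gene)
      conc <- tryCatch(concordance(fc, qp, scale = scale),
                       error = function(e) {
                         warn(paste0("concordance skipped for phase '", ph,
                                     "': ", conditionMessage(e)))
                         NULL
                       })
    }
    list(phase = ph, sf = sf, gene_signals = gs, fold_changes = fc,
         de = de, enrichment = enr, qpcr = qp, ref_stability = ref,
         concordance = conc)
  })
  names(per_phase) <- phases

  fold_changes <- purrr::map_dfr(per_phase, "fold_changes")
  summary <- purrr::map_dfr(per_phase, function(s) {
    tibble::tibble(
      phase = s$phase,
      scale_factor = s$sf$value,
      genes_summarized = dplyr::n_distinct(s$gene_signals$gene_id),
      genes_with_ratio = nrow(s$fold_changes),
      n_up = nrow(s$de$up),
      n_down = nrow(s$de$down),
      n_enriched_terms = if (is.null(s$enrichment)) NA_integer_ else
        sum(s$enrichment$adjusted_p <= alpha),
      concordance_r = if (is.null(s$concordance)) NA_real_ else
        s$concordance$r,
      concordance_n = if (is.null(s$concordance)) NA_integer_ else
        s$concordance$n
    )
  })

  run <- structure(
    list(
      fold_changes = fold_changes,
      gene_signals = purrr::map_dfr(per_phase, "gene_signals"),
      scale_factors = purrr::map(per_phase, "sf"),
      de = purrr::map(per_phase, "de"),
      enrichment = purrr::map(per_phase, "enrichment"),
      qpcr = purrr::map(per_phase, "qpcr"),
      ref_stability = purrr::map(per_phase, "ref_stability"),
      concordance = purrr::map(per_phase, "concordance"),
      summary = summary,
      experiment = experiment,
      annotation = annotation,
      ct = ct,
      probes = probes,
      params = list(threshold = threshold, strict = strict, method = method,
                    scale = scale, alpha = alpha, background = background,
                    seed = config$seed),
      config = config
    ),
    class = "mf_run"
  )
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' Write every stage output of a pipeline run
#'
#' Writes, deterministically: the input probe table, per-array gene
#' signals, per-phase fold-change results (fixed 6-decimal formatting),
#' enrichment and qPCR tables, the CT plate and annotation, a gene-by-phase
#' log2-ratio matrix suitable for any heatmap viewer, a JSON run summary,
#' and a text report. Re-running the same configuration and seed reproduces
#' every file byte for byte.
#'
#' @param run An `mf_run`.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_probe_table(run$probes, fp("probes.tsv"))
  readr::write_tsv(run$gene_signals, fp("gene_signals.tsv"), progress = FALSE)
  for (ph in names(run$de)) {
    write_results(run$fold_changes[run$fold_changes$phase == ph, ],
                  fp(paste0("results_", ph, ".tsv")))
    if (!is.null(run$enrichment[[ph]])) {
      readr::write_tsv(run$enrichment[[ph]],
                       fp(paste0("enrichment_", ph, ".tsv")), progress = FALSE)
    }
    if (!is.null(run$qpcr[[ph]])) {
      readr::write_tsv(run$qpcr[[ph]], fp(paste0("qpcr_", ph, ".tsv")),
                       progress = FALSE)
    }
  }
  if (!is.null(run$annotation)) {
    write_annotation(run$annotation, fp("annotation.tsv"))
  }
  if (!is.null(run$ct)) write_ct_table(run$ct, fp("ct.tsv"))
  readr::write_tsv(log2_ratio_matrix(run), fp("log2_matrix.tsv"),
                   progress = FALSE)
  jsonlite::write_json(run_summary_list(run), fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(pipeline_report(run), fp("report.txt"))
  invisible(outdir)
}

# The RunSummary as a plain list for JSON serialization.
run_summary_list <- function(run) {
  list(
    tool = "microfold",
    version = as.character(utils::packageVersion("microfold")),
    seed = run$params$seed,
    params = run$params[c("threshold", "strict", "method", "scale", "alpha",
                          "background")],
    config = unclass(run$config),
    phases = purrr::pmap(run$summary, function(...) list(...))
  )
}

#' Gene-by-contrast log2-ratio matrix
#'
#' Wide export of the per-phase log2 expression ratios (one column per
#' phase contrast), the standard input shape for heatmap viewers.
#'
#' @param run An `mf_run`.
#' @return A tibble, `gene_id` plus one `log2_<phase>` column per phase.
#' @export
log2_ratio_matrix <- function(run) {
  wide <- tidyr::pivot_wider(
    run$fold_changes[, c("gene_id", "phase", "log2_ratio")],
    names_from = "phase", values_from = "log2_ratio",
    names_prefix = "log2_")
  dplyr::arrange(wide, .data$gene_id)
}

#' Human-readable pipeline report
#'
#' Formats scale factors, DE counts, top enriched terms and concordance per
#' phase. When a phase has no DE genes, the report says so and omits the
#' term section.
#'
#' @param run An `mf_run`.
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly when `path` is given.
#' @export
pipeline_report <- function(run, path = NULL) {
  lines <- c("microfold run report",
             paste0("seed: ", run$params$seed,
                    "  threshold: ", ifelse(run$params$strict, ">", ">="),
                    " ", run$params$threshold, "-fold"))
  for (ph in run$summary$phase) {
    s <- run$summary[run$summary$phase == ph, ]
    lines <- c(lines, "",
               paste0("phase: ", ph),
               sprintf("  scale factor SF = %.6f", s$scale_factor),
               sprintf("  genes summarized: %d; with defined ratio: %d",
                       s$genes_summarized, s$genes_with_ratio))
    if (s$n_up + s$n_down == 0) {
      lines <- c(lines, "  zero DE genes at this threshold")
    } else {
      lines <- c(lines, sprintf("  DE genes: %d up, %d down", s$n_up, s$n_down))
      enr <- run$enrichment[[ph]]
      if (!is.null(enr) && nrow(enr) > 0) {
        top <- head(enr, 5)
        lines <- c(lines, "  top terms (BH-adjusted p):",
                   sprintf("    %s  %s  k=%d/K=%d  p.adj=%.3g",
                           top$term_id, top$term_label, top$k, top$K,
                           top$adjusted_p))
      }
    }
    if (!is.null(run$concordance[[ph]])) {
      lines <- c(lines,
                 sprintf("  microarray-qPCR concordance: R = %.3f (n = %d)",
                         run$concordance[[ph]]$r, run$concordance[[ph]]$n))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.mf_run <- function(x, ...) {
  cat("<mf_run>\n")
  print(x$summary)
  invisible(x)
}
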