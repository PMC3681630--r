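#' Simulation configuration for a replicated-probe array experiment
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults emulate a 5,003-gene bacterial expression array carrying five
#' identical replicate spots per gene, hybridized once per pooled condition
#' (control and treatment) in each of two growth phases, with phase-specific
#' spiked fold-change ranges and differential-expression fractions, a term
#' annotation with spiked enriched terms, and a matched qPCR panel with a
#' constant reference gene.
#'
#' Per-phase parameters (`de_fraction_up`, `de_fraction_down`, `fc_log2_min`,
#' `fc_log2_max`, `qpcr_genes`) accept a scalar (recycled) or one value per
#' phase. `array_scale` accepts a scalar or one value per array, arrays
#' ordered control-then-treatment within each phase.
#'
#' @param n_genes Number of genes on the array.
#' @param n_probe_reps Identical replicate spots per gene per array (>= 3).
#' @param phases Character vector of phase labels; one contrast per phase.
#' @param de_fraction_up,de_fraction_down Per-phase fractions of genes spiked
#'   up- or down-regulated. Defaults mirror a study in which roughly 111 of
#'   5,003 genes respond in the first phase and 721 in the second, split
#'   evenly between directions.
#' @param fc_log2_min,fc_log2_max Per-phase bounds (log2 units) of the
#'   uniform distribution of spiked absolute fold changes. Defaults span
#'   3-fold up to 16-fold (first phase) and 54-fold (second phase).
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of
#'   per-gene baseline log2 expression (arbitrary intensity units).
#' @param probe_affinity_sd SD (log2 units) of the per-probe affinity offset,
#'   fixed per (gene, replicate) across all arrays (same probe sequence).
#' @param noise_sd SD (log2 units) of independent per-spot measurement noise.
#' @param array_scale Multiplicative per-array intensity factor (scanner /
#'   labelling differences); what scale-factor normalization must undo.
#' @param outlier_prob Probability that a spot is an outlier.
#' @param outlier_log2_shift Magnitude (log2 units) of the symmetric shift
#'   applied to outlier spots.
#' @param signal_floor Positive floor (intensity units) applied to generated
#'   signals; floor hits are counted and reported.
#' @param n_terms,term_size_min,term_size_max Annotation model: number of
#'   terms and the uniform range of term sizes.
#' @param n_enriched_terms Number of terms per phase whose membership is
#'   biased toward that phase's differentially expressed genes.
#' @param enrichment_boost Sampling-weight multiplier applied to a phase's
#'   DE genes when drawing members of that phase's enriched terms.
#' @param qpcr_genes Per-phase number of target genes on the qPCR panel.
#'   Defaults mirror a validation of 19 and 23 genes in the two phases.
#' @param qpcr_ct_sd SD (cycles) of per-well CT noise.
#' @param qpcr_ref_ct True CT (cycles) of the reference gene in every
#'   condition (an abundant constant transcript such as 16S rRNA).
#' @param reference_gene Identifier used for the reference gene's wells.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output tables.
#' @return An object of class `mf_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 7)
#' cfg$n_probe_reps
#' @export
sim_config <- function(n_genes = 5003,
                       n_probe_reps = 5,
                       phases = c("acidogenic", "solventogenic"),
                       de_fraction_up = c(111, 721) / (2 * 5003),
                       de_fraction_down = c(111, 721) / (2 * 5003),
                       fc_log2_min = log2(3),
                       fc_log2_max = c(log2(16), log2(54)),
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       probe_affinity_sd = 0.15,
                       noise_sd = 0.2,
                       array_scale = c(1, 1.2, 1, 0.85),
                       outlier_prob = 0.01,
                       outlier_log2_shift = 4,
                       signal_floor = 1,
                       n_terms = 50,
                       term_size_min = 10,
                       term_size_max = 40,
                       n_enriched_terms = 5,
                       enrichment_boost = 50,
                       qpcr_genes = c(19, 23),
                       qpcr_ct_sd = 0.15,
                       qpcr_ref_ct = 12,
                       reference_gene = "ref_16S",
                       seed = 1L) {
  n_phases <- length(phases)
  if (n_phases < 1 || anyDuplicated(phases) > 0) {
    abort("'phases' must be a non-empty vector of distinct labels")
  }
  if (n_genes < 1) abort("'n_genes' must be >= 1")
  if (n_probe_reps < 3) abort("'n_probe_reps' must be >= 3 (trimming needs 3)")

  de_fraction_up <- recycle_phase(de_fraction_up, n_phases, "de_fraction_up")
  de_fraction_down <- recycle_phase(de_fraction_down, n_phases, "de_fraction_down")
  fc_log2_min <- recycle_phase(fc_log2_min, n_phases, "fc_log2_min")
  fc_log2_max <- recycle_phase(fc_log2_max, n_phases, "fc_log2_max")
  qpcr_genes <- recycle_phase(qpcr_genes, n_phases, "qpcr_genes")

  props <- c(de_fraction_up, de_fraction_down, outlier_prob)
  if (any(props < 0 | props > 1)) {
    abort("all proportions must lie in [0, 1]")
  }
  if (any(de_fraction_up + de_fraction_down >= 1)) {
    abort("de_fraction_up + de_fraction_down must be < 1 in every phase")
  }
  if (any(fc_log2_min < 0)) abort("'fc_log2_min' must be >= 0")
  if (any(fc_log2_max < fc_log2_min)) {
    abort("'fc_log2_max' must be >= 'fc_log2_min' in every phase")
  }
  if (any(c(baseline_log2_sd, probe_affinity_sd, noise_sd, qpcr_ct_sd) < 0)) {
    abort("standard deviations must be >= 0")
  }
  check_positive_scalar(signal_floor, "signal_floor")
  n_arrays <- 2L * n_phases
  if (length(array_scale) == 1) array_scale <- rep(array_scale, n_arrays)
  if (length(array_scale) != n_arrays) {
    abort(paste0("'array_scale' must have length 1 or ", n_arrays,
                 " (control, treatment per phase)"))
  }
  if (any(array_scale <= 0)) abort("'array_scale' must be positive")
  if (term_size_min < 1 || term_size_max < term_size_min) {
    abort("term sizes must satisfy 1 <= term_size_min <= term_size_max")
  }
  if (term_size_max > n_genes) abort("'term_size_max' cannot exceed n_genes")
  if (n_enriched_terms * n_phases > n_terms) {
    abort("'n_enriched_terms' per phase cannot exceed n_terms in total")
  }
  if (enrichment_boost < 1) abort("'enrichment_boost' must be >= 1")
  if (any(qpcr_genes > n_genes)) abort("'qpcr_genes' cannot exceed n_genes")
  seed <- as.integer(seed)
  if (is.na(seed)) abort("'seed' must be an integer")

  structure(
    list(
      n_genes = as.integer(n_genes),
      n_probe_reps = as.integer(n_probe_reps),
      phases = as.character(phases),
      de_fraction_up = de_fraction_up,
      de_fraction_down = de_fraction_down,
      fc_log2_min = fc_log2_min,
      fc_log2_max = fc_log2_max,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      probe_affinity_sd = probe_affinity_sd,
      noise_sd = noise_sd,
      array_scale = array_scale,
      outlier_prob = outlier_prob,
      outlier_log2_shift = outlier_log2_shift,
      signal_floor = signal_floor,
      n_terms = as.integer(n_terms),
      term_size_min = as.integer(term_size_min),
      term_size_max = as.integer(term_size_max),
      n_enriched_terms = as.integer(n_enriched_terms),
      enrichment_boost = enrichment_boost,
      qpcr_genes = as.integer(qpcr_genes),
      qpcr_ct_sd = qpcr_ct_sd,
      qpcr_ref_ct = qpcr_ref_ct,
      reference_gene = reference_gene,
      seed = seed
    ),
    class = "mf_config"
  )
}

#' @export
print.mf_config <- function(x, ...) {
  cat("<mf_config>\n")
  cat("  genes:", x$n_genes, " probe replicates:", x$n_probe_reps, "\n")
  cat("  phases:", paste(x$phases, collapse = ", "), "\n")
  cat("  DE fractions (up/down):",
      paste(sprintf("%.4f/%.4f", x$de_fraction_up, x$de_fraction_down),
            collapse = "; "), "\n")
  cat("  spiked |log2 FC| in:",
      paste(sprintf("[%.2f, %.2f]", x$fc_log2_min, x$fc_log2_max),
            collapse = "; "), "\n")
  cat("  noise_sd:", x$noise_sd, " probe_affinity_sd:", x$probe_affinity_sd,
      " outlier_prob:", x$outlier_prob, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
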