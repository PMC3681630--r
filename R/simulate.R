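#' Simulate a replicated-probe microarray experiment with known truth
#'
#' Generates spot-level intensity tables for one single-channel array per
#' pooled condition (control, treatment) in each growth phase, together with
#' the ground truth needed to test every downstream stage: per-gene true
#' log2 fold changes and DE labels, per-spot outlier flags, a gene-to-term
#' annotation with spiked enriched terms, and a matched qPCR CT plate.
#'
#' The generative model for a spot is
#' \deqn{signal(g,r,a) = s_a \cdot 2^{\,b_g + f_{g}\,[a\ is\ treatment] +
#'   \alpha_{g,r} + \epsilon_{g,r,a}}}
#' where \eqn{s_a} is the per-array scale factor, \eqn{b_g} the gene
#' baseline, \eqn{f_g} the spiked log2 fold change (0 for non-DE genes),
#' \eqn{\alpha_{g,r}} a probe-affinity offset fixed across arrays (the same
#' physical probe sequence is printed on every array), and \eqn{\epsilon}
#' independent per-spot noise. With probability `outlier_prob` a spot's log2
#' signal is additionally shifted by `outlier_log2_shift` with random sign.
#' Signals are clamped at `signal_floor`; the number of floor hits is
#' reported.
#'
#' Two structural choices make the spiked truth recoverable exactly by
#' global-mean scale-factor normalization in the noise-free limit: DE gene
#' sets are disjoint across phases, and within each phase the baselines of
#' up- and down-spiked genes are shifted by equal and opposite log2 amounts
#' so that spiked regulation conserves the array's total signal (the
#' assumption under which a single global scale factor is the correct
#' normalization). The shift cancels in every treatment/control ratio, so
#' no gene's true fold change is affected.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `mf_experiment`: a list with elements
#'   \describe{
#'     \item{probes}{spot-level tibble (`gene_id`, `probe_index`,
#'       `array_id`, `condition`, `phase`, `signal`)}
#'     \item{truth}{list with `genes` (per gene and phase: baseline,
#'       `true_log2_fc`, `de_label`), `terms` (per term and phase:
#'       `enriched`), `spots` (per-spot `outlier` flag) and
#'       `n_floor_hits`}
#'     \item{annotation}{long tibble `term_id`, `term_label`, `gene_id`}
#'     \item{ct}{qPCR CT tibble from [simulate_qpcr()]}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' exp <- simulate_experiment(sim_config(n_genes = 50, seed = 1))
#' dplyr::count(exp$probes, array_id)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "mf_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  n_reps <- config$n_probe_reps
  phases <- config$phases
  n_phases <- length(phases)
  width <- max(4L, nchar(as.character(n_genes)))
  genes <- sprintf("Cbei_%0*d", width, seq_len(n_genes))

  baseline <- rnorm(n_genes, config$baseline_log2_mean, config$baseline_log2_sd)
  # one affinity per physical probe sequence, shared by all arrays
  affinity <- matrix(rnorm(n_genes * n_reps, 0, config$probe_affinity_sd),
                     nrow = n_genes)

  # Spike DE genes phase by phase. DE sets are disjoint across phases, and
  # within a phase the baselines of up- and down-spiked genes receive equal
  # and opposite log2 shifts chosen so the spiked regulation is
  # mass-balanced: the treatment array's expected mean signal equals the
  # control's, the condition under which global-mean scale-factor
  # normalization recovers fold changes exactly. The shift cancels in every
  # per-gene ratio, so no gene's true fold change is altered.
  fc_mat <- matrix(0, nrow = n_genes, ncol = n_phases)
  lab_mat <- matrix("none", nrow = n_genes, ncol = n_phases)
  available <- seq_len(n_genes)
  for (p in seq_len(n_phases)) {
    n_up <- round(config$de_fraction_up[p] * n_genes)
    n_dn <- round(config$de_fraction_down[p] * n_genes)
    if (n_up + n_dn > length(available)) {
      abort("DE fractions too large for disjoint spiking across phases")
    }
    idx <- if (n_up + n_dn > 0) {
      available[sample.int(length(available), n_up + n_dn)]
    } else integer(0)
    available <- setdiff(available, idx)
    up_idx <- idx[seq_len(n_up)]
    dn_idx <- idx[n_up + seq_len(n_dn)]
    if (n_up > 0) {
      fc_mat[up_idx, p] <- runif(n_up, config$fc_log2_min[p],
                                 config$fc_log2_max[p])
      lab_mat[up_idx, p] <- "up"
    }
    if (n_dn > 0) {
      fc_mat[dn_idx, p] <- -runif(n_dn, config$fc_log2_min[p],
                                  config$fc_log2_max[p])
      lab_mat[dn_idx, p] <- "down"
    }
    if (n_up > 0 && n_dn > 0) {
      s_up <- sum(2^baseline[up_idx] * (2^fc_mat[up_idx, p] - 1))
      s_dn <- sum(2^baseline[dn_idx] * (2^fc_mat[dn_idx, p] - 1))
      if (s_up > 0 && s_dn < 0) {
        d <- log2(s_up / -s_dn) / 2
        baseline[up_idx] <- baseline[up_idx] - d
        baseline[dn_idx] <- baseline[dn_idx] + d
      }
    }
  }
  truth_genes <- purrr::map_dfr(seq_len(n_phases), function(p) {
    tibble::tibble(gene_id = genes, phase = phases[p],
                   baseline_log2 = baseline, true_log2_fc = fc_mat[, p],
                   de_label = lab_mat[, p])
  })

  arrays <- tibble::tibble(
    phase = rep(phases, each = 2L),
    condition = rep(c("control", "treatment"), n_phases),
    array_id = paste(rep(phases, each = 2L),
                     rep(c("control", "treatment"), n_phases), sep = "_"),
    scale = config$array_scale
  )

  n_spots <- n_genes * n_reps
  spot_gene <- rep(seq_len(n_genes), each = n_reps)
  spot_rep <- rep(seq_len(n_reps), times = n_genes)
  aff_vec <- affinity[cbind(spot_gene, spot_rep)]
  n_floor_hits <- 0L

  per_array <- purrr::pmap(arrays, function(phase, condition, array_id, scale) {
    fc_vec <- truth_genes$true_log2_fc[truth_genes$phase == phase][spot_gene]
    log2_sig <- baseline[spot_gene] +
      (condition == "treatment") * fc_vec +
      aff_vec +
      rnorm(n_spots, 0, config$noise_sd)
    out_flag <- rbinom(n_spots, 1L, config$outlier_prob) == 1L
    out_sign <- sample(c(-1, 1), n_spots, replace = TRUE)
    log2_sig <- log2_sig + ifelse(out_flag,
                                  out_sign * config$outlier_log2_shift, 0)
    signal <- scale * 2^log2_sig
    if (any(!is.finite(signal))) {
      abort(paste0("non-finite signal generated on array ", array_id,
                   "; check baseline/fold-change magnitudes"))
    }
    floored <- signal < config$signal_floor
    n_floor_hits <<- n_floor_hits + sum(floored)
    signal <- pmax(signal, config$signal_floor)
    list(
      probes = tibble::tibble(
        gene_id = genes[spot_gene], probe_index = spot_rep,
        array_id = array_id, condition = condition, phase = phase,
        signal = signal),
      spots = tibble::tibble(
        gene_id = genes[spot_gene], probe_index = spot_rep,
        array_id = array_id, outlier = out_flag)
    )
  })
  probes <- purrr::map_dfr(per_array, "probes")
  spots <- purrr::map_dfr(per_array, "spots")
  if (n_floor_hits > 0) {
    inform(paste0(n_floor_hits, " spot(s) clamped to the signal floor (",
                  config$signal_floor, ")"))
  }

  ann <- simulate_annotation(truth_genes, genes, config)

  truth <- list(genes = truth_genes, terms = ann$terms, spots = spots,
                n_floor_hits = n_floor_hits)
  ct <- simulate_qpcr(truth, config)

  structure(
    list(probes = probes, truth = truth, annotation = ann$annotation,
         ct = ct, config = config),
    class = "mf_experiment"
  )
}

# Term annotation with per-phase spiked enriched terms. Enriched terms draw
# members with weight `enrichment_boost` on that phase's DE genes.
simulate_annotation <- function(truth_genes, genes, config) {
  n_terms <- config$n_terms
  n_phases <- length(config$phases)
  term_ids <- sprintf("TERM_%03d", seq_len(n_terms))
  enriched_phase <- rep(NA_character_, n_terms)
  if (config$n_enriched_terms > 0) {
    for (p in seq_len(n_phases)) {
      idx <- (p - 1L) * config$n_enriched_terms + seq_len(config$n_enriched_terms)
      enriched_phase[idx] <- config$phases[p]
    }
  }
  sizes <- sample(seq(config$term_size_min, config$term_size_max),
                  n_terms, replace = TRUE)
  members <- purrr::map(seq_len(n_terms), function(t) {
    w <- rep(1, config$n_genes)
    if (!is.na(enriched_phase[t])) {
      de <- truth_genes$de_label != "none" &
        truth_genes$phase == enriched_phase[t]
      w[match(truth_genes$gene_id[de], genes)] <- config$enrichment_boost
    }
    sort(sample(genes, sizes[t], prob = w))
  })
  annotation <- tibble::tibble(
    term_id = rep(term_ids, sizes),
    term_label = rep(paste0("term ", seq_len(n_terms)), sizes),
    gene_id = unlist(members)
  )
  terms <- tidyr::expand_grid(term_id = term_ids, phase = config$phases)
  terms$enriched <- enriched_phase[match(terms$term_id, term_ids)] == terms$phase
  terms$enriched[is.na(terms$enriched)] <- FALSE
  list(annotation = annotation, terms = terms)
}

#' Simulate qPCR CT plates matched to simulated array truth
#'
#' Draws a per-phase panel of target genes stratified across up-, down- and
#' non-regulated genes, and generates triplicate CT wells per gene and
#' condition under the comparative-CT model: a gene's CT decreases one cycle
#' per doubling of its expression, so
#' \eqn{CT(g, cond) = o_g - \log_2 expr(g, cond) + N(0, \sigma^2)} with a
#' gene-specific offset \eqn{o_g}. The reference gene is generated at a
#' constant true CT in every condition.
#'
#' @param truth The `truth` element of an [simulate_experiment()] result
#'   (only `truth$genes` is used).
#' @param config The [sim_config()] used to generate the experiment.
#' @return A CT tibble with columns `phase`, `condition`, `gene_id`, `well`,
#'   `ct` (three wells per gene and condition, reference gene included in
#'   every condition).
#' @export
simulate_qpcr <- function(truth, config) {
  stopifnot(inherits(config, "mf_config"))
  set.seed(config$seed + 9973L)
  tg <- truth$genes
  n_wells <- 3L
  purrr::map_dfr(seq_along(config$phases), function(p) {
    ph <- config$phases[p]
    tp <- tg[tg$phase == ph, ]
    n_q <- config$qpcr_genes[p]
    up <- tp$gene_id[tp$de_label == "up"]
    dn <- tp$gene_id[tp$de_label == "down"]
    none <- tp$gene_id[tp$de_label == "none"]
    n_up <- min(length(up), ceiling(0.4 * n_q))
    n_dn <- min(length(dn), ceiling(0.3 * n_q))
    n_none <- min(length(none), n_q - n_up - n_dn)
    panel <- c(
      if (n_up > 0) sample(up, n_up),
      if (n_dn > 0) sample(dn, n_dn),
      if (n_none > 0) sample(none, n_none)
    )
    rows <- tp[match(panel, tp$gene_id), ]
    offset <- 24 + rows$baseline_log2
    per_cond <- purrr::map_dfr(c("control", "treatment"), function(cond) {
      expr <- rows$baseline_log2 +
        (cond == "treatment") * rows$true_log2_fc
      target_ct <- rep(offset - expr, each = n_wells) +
        rnorm(length(panel) * n_wells, 0, config$qpcr_ct_sd)
      ref_ct <- config$qpcr_ref_ct + rnorm(n_wells, 0, config$qpcr_ct_sd)
      tibble::tibble(
        phase = ph, condition = cond,
        gene_id = c(rep(panel, each = n_wells),
                    rep(config$reference_gene, n_wells)),
        well = c(rep(seq_len(n_wells), length(panel)), seq_len(n_wells)),
        ct = c(target_ct, ref_ct)
      )
    })
    per_cond
  })
}

#' @export
print.mf_experiment <- function(x, ...) {
  cat("<mf_experiment>\n")
  cat("  ", x$config$n_genes, " genes x ", x$config$n_probe_reps,
      " probe replicates on ", dplyr::n_distinct(x$probes$array_id),
      " arrays\n", sep = "")
  de <- dplyr::count(x$truth$genes, .data$phase,
                     de = .data$de_label != "none")
  for (ph in x$config$phases) {
    n_de <- sum(de$n[de$phase == ph & de$de])
    cat("  ", ph, ": ", n_de, " spiked DE genes\n", sep = "")
  }
  cat("  terms: ", x$config$n_terms, " (",
      sum(x$truth$terms$enriched), " phase-enriched)\n", sep = "")
  invisible(x)
}
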