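# Shared fixtures: small configurations and hand-built tables.

# A small experiment configuration; override any field via ...
tiny_config <- function(..., seed = 42) {
  args <- utils::modifyList(list(
    n_genes = 60, n_probe_reps = 5,
    de_fraction_up = 0.1, de_fraction_down = 0.1,
    fc_log2_min = log2(3) + 0.2, fc_log2_max = 4,
    n_terms = 8, term_size_min = 5, term_size_max = 15,
    n_enriched_terms = 2, enrichment_boost = 80,
    qpcr_genes = 10, seed = seed), list(...))
  do.call(sim_config, args)
}

# Noise-free variant: deterministic signals up to the spiked fold changes.
noiseless_config <- function(..., seed = 42) {
  args <- utils::modifyList(list(noise_sd = 0, probe_affinity_sd = 0,
                                 outlier_prob = 0, qpcr_ct_sd = 0,
                                 seed = seed), list(...))
  do.call(tiny_config, args)
}

# A minimal hand-built probe table: one gene per entry of `signals`,
# replicated over the given arrays.
probe_table <- function(signals, array_id = "a1", condition = "control",
                        phase = "p1") {
  purrr::map_dfr(seq_along(signals), function(g) {
    tibble::tibble(
      gene_id = names(signals)[g] %||% paste0("g", g),
      probe_index = seq_along(signals[[g]]),
      array_id = array_id, condition = condition, phase = phase,
      signal = signals[[g]]
    )
  })
}

# Two-array table (control + treatment) from per-gene signal vectors.
two_array_table <- function(control, treatment, phase = "p1") {
  dplyr::bind_rows(
    probe_table(control, array_id = "ctl", condition = "control", phase = phase),
    probe_table(treatment, array_id = "trt", condition = "treatment", phase = phase)
  )
}

# Independent trimmed-mean oracle: sort, drop first and last, average.
oracle_trim <- function(x) {
  if (length(x) < 4) return(mean(x))
  s <- sort(x)
  mean(s[2:(length(s) - 1)])
}

# Independent hypergeometric upper-tail oracle by direct combinatorial sum.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
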