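test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_probe_reps = 2), ">= 3")
  expect_error(sim_config(de_fraction_up = 0.6, de_fraction_down = 0.5),
               "< 1")
  expect_error(sim_config(fc_log2_min = -1), ">= 0")
  expect_error(sim_config(de_fraction_up = 1.2), "proportions")
  expect_error(sim_config(array_scale = c(1, 2, 3)), "array_scale")
  expect_error(tiny_config(term_size_max = 1000), "n_genes")
})

test_that("simulated experiments are deterministic and structurally valid", {
  cfg <- tiny_config(seed = 7)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$probes, e2$probes)
  expect_identical(e1$ct, e2$ct)
  expect_identical(e1$annotation, e2$annotation)

  # exactly n_probe_reps rows per (gene, array), every gene on every array
  expect_silent(validate_probe_table(e1$probes, cfg$n_probe_reps))
  expect_equal(dplyr::n_distinct(e1$probes$array_id), 4)
  expect_true(all(e1$probes$signal >= cfg$signal_floor))

  # a different seed changes the data
  e3 <- simulate_experiment(tiny_config(seed = 8))
  expect_false(identical(e1$probes$signal, e3$probes$signal))
})

test_that("spiked truth is consistent with DE labels and configured fractions", {
  cfg <- tiny_config(seed = 11)
  tg <- simulate_experiment(cfg)$truth$genes
  for (p in seq_along(cfg$phases)) {
    tp <- tg[tg$phase == cfg$phases[p], ]
    expect_equal(sum(tp$de_label == "up"),
                 round(cfg$de_fraction_up[p] * cfg$n_genes))
    expect_equal(sum(tp$de_label == "down"),
                 round(cfg$de_fraction_down[p] * cfg$n_genes))
    expect_true(all(tp$true_log2_fc[tp$de_label == "up"] >= cfg$fc_log2_min[p]))
    expect_true(all(tp$true_log2_fc[tp$de_label == "down"] <= -cfg$fc_log2_min[p]))
    expect_true(all(tp$true_log2_fc[tp$de_label == "none"] == 0))
  }
})

test_that("noise-free signals follow the closed-form generative model", {
  # no gene effect: every treatment/control spot ratio is the array-scale ratio
  cfg0 <- noiseless_config(de_fraction_up = 0, de_fraction_down = 0,
                           array_scale = c(1, 1.5, 2, 0.5))
  probes <- simulate_experiment(cfg0)$probes
  for (p in seq_along(cfg0$phases)) {
    ph <- cfg0$phases[p]
    ctl <- probes[probes$phase == ph & probes$condition == "control", ]
    trt <- probes[probes$phase == ph & probes$condition == "treatment", ]
    scale_ratio <- cfg0$array_scale[2 * p] / cfg0$array_scale[2 * p - 1]
    expect_equal(trt$signal / ctl$signal,
                 rep(scale_ratio, nrow(ctl)), tolerance = 1e-12)
  }

  # a spiked gene's spot ratio is 2^fc times the array-scale ratio
  cfg1 <- noiseless_config(de_fraction_up = 1 / 60, de_fraction_down = 0,
                           fc_log2_min = 2, fc_log2_max = 2,
                           array_scale = c(1, 1.5, 1, 1.5))
  e1 <- simulate_experiment(cfg1)
  tg <- e1$truth$genes
  spiked <- tg$gene_id[tg$phase == cfg1$phases[1] & tg$de_label == "up"]
  expect_length(spiked, 1)
  ph <- cfg1$phases[1]
  sel <- e1$probes$phase == ph & e1$probes$gene_id == spiked
  ctl <- e1$probes[sel & e1$probes$condition == "control", ]
  trt <- e1$probes[sel & e1$probes$condition == "treatment", ]
  expect_equal(trt$signal / ctl$signal, rep(4 * 1.5, nrow(ctl)),
               tolerance = 1e-12)
})

test_that("outlier contamination rate is calibrated to outlier_prob", {
  cfg <- tiny_config(n_genes = 500, outlier_prob = 0.02, seed = 13)
  spots <- simulate_experiment(cfg)$truth$spots
  n <- nrow(spots)
  frac <- mean(spots$outlier)
  se <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(frac - 0.02), 3 * se)
})

test_that("qPCR plates follow the comparative-CT generative model", {
  cfg <- noiseless_config(seed = 21)
  e <- simulate_experiment(cfg)
  ct <- e$ct
  tg <- e$truth$genes

  # triplicate wells per (gene, condition)
  wells <- dplyr::count(ct, phase, condition, gene_id)
  expect_true(all(wells$n == 3))

  # reference gene at the configured CT in every condition (zero noise)
  ref <- ct[ct$gene_id == cfg$reference_gene, ]
  expect_equal(ref$ct, rep(cfg$qpcr_ref_ct, nrow(ref)))

  # treatment CT is true_log2_fc cycles below control CT
  means <- dplyr::summarise(
    dplyr::group_by(ct[ct$gene_id != cfg$reference_gene, ],
                    phase, gene_id, condition),
    ct = mean(ct), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "condition",
                             values_from = "ct")
  truth_fc <- tg$true_log2_fc[match(paste(wide$phase, wide$gene_id),
                                    paste(tg$phase, tg$gene_id))]
  expect_equal(wide$control - wide$treatment, truth_fc, tolerance = 1e-12)

  # non-DE panel genes have identical CT in both conditions
  flat <- wide[truth_fc == 0, ]
  expect_gt(nrow(flat), 0)
  expect_equal(flat$control, flat$treatment)
})
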