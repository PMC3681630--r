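# Hand-built CT plate: target measured in both conditions against a
# reference, optional extra genes.
ct_plate <- function(target_trt, target_ctl, ref_trt = 10, ref_ctl = 10,
                     gene = "tgt", ref = "ref") {
  tibble::tibble(
    condition = rep(c("treatment", "control"), each = 2),
    gene_id = rep(c(gene, ref), 2),
    well = 1L,
    ct = c(target_trt, ref_trt, target_ctl, ref_ctl))
}

test_that("the comparative-CT worked examples are exact", {
  r <- delta_delta_ct(ct_plate(20, 24), "ref")
  expect_equal(r$delta_delta_ct, -4)
  expect_equal(r$relative_expression, 16)
  expect_equal(r$qpcr_fold_change, 16)

  sym <- delta_delta_ct(ct_plate(24, 20), "ref")
  expect_equal(sym$delta_delta_ct, 4)
  expect_equal(sym$relative_expression, 1 / 16)
  expect_equal(sym$qpcr_fold_change, -16)

  flat <- delta_delta_ct(ct_plate(22, 22), "ref")
  expect_equal(flat$delta_delta_ct, 0)
  expect_equal(flat$relative_expression, 1)
})

test_that("well replicates are averaged before delta-CT", {
  ct <- tibble::tibble(
    condition = rep(c("treatment", "control"), each = 4),
    gene_id = rep(c("tgt", "tgt", "tgt", "ref"), 2),
    well = rep(c(1L, 2L, 3L, 1L), 2),
    ct = c(19, 20, 21, 10, 24, 24, 24, 10))
  r <- delta_delta_ct(ct, "ref")
  expect_equal(r$delta_delta_ct, (20 - 10) - (24 - 10))
  expect_equal(r$relative_expression, 16)
})

test_that("ddCT is invariant to constant CT shifts within a condition", {
  set.seed(5)
  base <- purrr::map_dfr(paste0("g", 1:6), function(g) {
    ct_plate(runif(1, 18, 26), runif(1, 18, 26),
             ref_trt = 12, ref_ctl = 12, gene = g)
  })
  base <- dplyr::distinct(base, condition, gene_id, well, .keep_all = TRUE)
  r0 <- delta_delta_ct(base, "ref")
  shifted <- dplyr::mutate(base, ct = ct + ifelse(condition == "treatment",
                                                  2.7, 0))
  r1 <- delta_delta_ct(shifted, "ref")
  expect_equal(r1$delta_delta_ct, r0$delta_delta_ct, tolerance = 1e-12)
  # exactness identity: 2^-ddCT * 2^ddCT = 1
  expect_equal(r0$relative_expression * 2^r0$delta_delta_ct,
               rep(1, nrow(r0)))
})

test_that("missing measurements are handled per the contract", {
  ct <- ct_plate(20, 24)
  extra <- tibble::tibble(condition = "treatment", gene_id = "only_trt",
                          well = 1L, ct = 25)
  expect_warning(r <- delta_delta_ct(dplyr::bind_rows(ct, extra), "ref"),
                 "only_trt")
  expect_equal(r$gene_id, "tgt")
  expect_error(delta_delta_ct(ct, "nope"), "reference gene")
  expect_error(delta_delta_ct(ct[ct$condition == "control", ], "ref"),
               "condition 'treatment'")
})

test_that("reference stability reports per-condition means and a verdict", {
  ct <- ct_plate(20, 24, ref_trt = 10, ref_ctl = 10)
  s <- reference_stability(ct, "ref")
  expect_equal(s$max_diff, 0)
  expect_true(s$pass)

  drift <- ct_plate(20, 24, ref_trt = 11, ref_ctl = 10)
  s2 <- reference_stability(drift, "ref", tolerance = 0.5)
  expect_equal(s2$max_diff, 1)
  expect_false(s2$pass)

  expect_warning(s3 <- reference_stability(
    ct[ct$condition == "control", ], "ref"), "single condition")
  expect_equal(s3$max_diff, 0)
  expect_true(s3$pass)

  expect_error(reference_stability(ct, "absent"), "missing")
})

test_that("concordance recovers exact and negated agreement", {
  arr <- tibble::tibble(gene_id = paste0("g", 1:5),
                        fold_change = c(4, -3, 8, -6, 2),
                        log2_ratio = log2(c(4, 1 / 3, 8, 1 / 6, 2)))
  qp_same <- tibble::tibble(gene_id = arr$gene_id,
                            qpcr_fold_change = arr$fold_change,
                            delta_delta_ct = -arr$log2_ratio)
  same <- concordance(arr, qp_same)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_equal(same$n, 5)
  expect_equal(same$slope, 1, tolerance = 1e-12)

  qp_neg <- dplyr::mutate(qp_same, qpcr_fold_change = -qpcr_fold_change,
                          delta_delta_ct = -delta_delta_ct)
  expect_equal(concordance(arr, qp_neg)$r, -1, tolerance = 1e-12)
  expect_equal(concordance(arr, qp_neg, scale = "log2")$r, -1,
               tolerance = 1e-12)

  expect_error(concordance(arr[1:2, ], qp_same), ">= 3")
  flat <- dplyr::mutate(qp_same, qpcr_fold_change = 1)
  expect_error(concordance(arr, flat), "zero variance")
})

test_that("a noise-free experiment gives perfect cross-platform agreement", {
  # the signed-fold scale jumps between +1 and -1 at ratio 1, so exactness
  # is asserted on the continuous log2 scale; on the fold scale it is
  # asserted for DE genes, which sit far from the jump
  run <- run_pipeline(noiseless_config(seed = 29))
  for (ph in names(run$concordance)) {
    conc <- concordance(run$fold_changes[run$fold_changes$phase == ph, ],
                        run$qpcr[[ph]], scale = "log2")
    expect_equal(conc$r, 1, tolerance = 1e-9)
    tg <- run$experiment$truth$genes
    tg <- tg[tg$phase == ph, ]
    truth_lfc <- tg$true_log2_fc[match(conc$data$gene_id, tg$gene_id)]
    expect_equal(conc$data$array_value, truth_lfc, tolerance = 1e-9)
    expect_equal(conc$data$qpcr_value, truth_lfc, tolerance = 1e-9)

    fold <- run$concordance[[ph]]
    de_ids <- tg$gene_id[tg$de_label != "none"]
    sel <- fold$data$gene_id %in% de_ids
    truth_fold <- signed_fold_change(
      2^tg$true_log2_fc[match(fold$data$gene_id[sel], tg$gene_id)])
    expect_equal(fold$data$array_value[sel], truth_fold, tolerance = 1e-9)
    expect_equal(fold$data$qpcr_value[sel], truth_fold, tolerance = 1e-9)
  }
})

test_that("concordance degrades as qPCR noise grows", {
  mean_r <- vapply(c(0.05, 0.6), function(sd) {
    rs <- vapply(1:8, function(i) {
      run <- run_pipeline(tiny_config(n_genes = 120, noise_sd = 0.05,
                                      qpcr_ct_sd = sd, qpcr_genes = 12,
                                      seed = 500 + i))
      mean(run$summary$concordance_r, na.rm = TRUE)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_gt(mean_r[1], mean_r[2])
})
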