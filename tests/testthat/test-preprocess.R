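test_that("array means and scale factors follow the SF definition", {
  tbl <- two_array_table(list(g1 = c(100, 200, 300)),
                         list(g1 = c(100, 150, 200)))
  expect_equal(array_mean_signal(tbl, "ctl"), 200)
  expect_equal(array_mean_signal(tbl, "trt"), 150)
  expect_error(array_mean_signal(tbl, "nope"), "unknown array")

  sf <- compute_scale_factor(tbl, "ctl", "trt")
  expect_s3_class(sf, "mf_scale_factor")
  expect_equal(sf$value, 200 / 150)
  expect_equal(sf$control_mean, 200)
  expect_equal(sf$treatment_mean, 150)

  # identical arrays give SF = 1; swapping gives the reciprocal
  same <- two_array_table(list(g1 = c(5, 5, 5)), list(g1 = c(5, 5, 5)))
  expect_equal(compute_scale_factor(same, "ctl", "trt")$value, 1)
  swapped <- compute_scale_factor(tbl, "trt", "ctl")
  expect_equal(sf$value * swapped$value, 1, tolerance = 1e-12)
})

test_that("applying the scale factor equalizes array means and is targeted", {
  tbl <- two_array_table(list(g1 = c(10, 20, 30), g2 = c(40, 50, 60)),
                         list(g1 = c(5, 15, 25), g2 = c(35, 45, 55)))
  sf <- compute_scale_factor(tbl, "ctl", "trt")
  adj <- apply_scale_factor(tbl, "trt", sf)
  # control spots untouched, treatment spots multiplied by SF
  expect_equal(adj$signal[adj$array_id == "ctl"],
               tbl$signal[tbl$array_id == "ctl"])
  expect_equal(adj$signal[adj$array_id == "trt"],
               tbl$signal[tbl$array_id == "trt"] * sf$value)
  # post-condition: adjusted treatment mean equals control mean
  expect_equal(array_mean_signal(adj, "trt"), array_mean_signal(adj, "ctl"),
               tolerance = 1e-12)
  # SF = 1 leaves the table unchanged
  expect_equal(apply_scale_factor(tbl, "trt", 1)$signal, tbl$signal)
})

test_that("trimmed mean drops one maximum and one minimum, ties included", {
  cases <- list(
    list(x = c(10, 2, 8, 100, 6), want = 8),
    list(x = c(5, 5, 5, 5, 5), want = 5),
    list(x = c(1, 1, 1, 1, 10), want = 1),
    list(x = c(2, 4, 9, 11), want = (4 + 9) / 2),  # 4 reps: average middle two
    list(x = c(3, 7, 20), want = 10)               # 3 reps: untrimmed mean
  )
  for (case in cases) {
    tbl <- probe_table(list(g = case$x))
    got <- trimmed_mean_summarize(tbl)
    expect_equal(got$signal, case$want)
    expect_equal(got$n_used + got$n_discarded, length(case$x))
  }
})

test_that("trimmed mean equals the sort-and-average oracle on random tuples", {
  set.seed(101)
  n <- 500
  xs <- lapply(seq_len(n), function(i) {
    if (i %% 3 == 0) sample(1:4, 5, replace = TRUE)  # force ties
    else round(runif(5, 0, 1000), 2)
  })
  tbl <- probe_table(setNames(xs, sprintf("g%03d", seq_len(n))))
  got <- trimmed_mean_summarize(tbl)
  # zero-padded ids sort in input order, so rows align with xs
  expect_identical(got$signal, vapply(xs, oracle_trim, numeric(1)))
})

test_that("trimmed mean is robust to extreme replicates and scale-equivariant", {
  set.seed(7)
  x <- c(2, 9, 14, 21, 30)
  base <- trimmed_mean_summarize(probe_table(list(g = x)))$signal
  # inflating the unique maximum (or deflating the minimum) changes nothing
  expect_equal(trimmed_mean_summarize(
    probe_table(list(g = c(2, 9, 14, 21, 1e9))))$signal, base)
  expect_equal(trimmed_mean_summarize(
    probe_table(list(g = c(0, 9, 14, 21, 30))))$signal, base)
  # scale equivariance
  for (c_mult in c(0.5, 3, 100)) {
    expect_equal(trimmed_mean_summarize(
      probe_table(list(g = c_mult * x)))$signal, c_mult * base)
  }
})

test_that("summaries stay within the replicate range and groups under 3 are dropped", {
  e <- simulate_experiment(tiny_config(seed = 31))
  gs <- trimmed_mean_summarize(e$probes)
  rng <- dplyr::summarise(dplyr::group_by(e$probes, gene_id, array_id),
                          lo = min(signal), hi = max(signal),
                          .groups = "drop")
  j <- dplyr::inner_join(gs, rng, by = c("gene_id", "array_id"))
  expect_true(all(j$signal >= j$lo & j$signal <= j$hi))
  expect_true(all(gs$n_used == 3 & gs$n_discarded == 2))

  short <- dplyr::bind_rows(
    probe_table(list(g1 = c(1, 2, 3, 4, 5))),
    tibble::tibble(gene_id = "g2", probe_index = 1:2, array_id = "a1",
                   condition = "control", phase = "p1", signal = c(7, 8)))
  expect_warning(got <- trimmed_mean_summarize(short), "unsummarizable")
  expect_equal(got$gene_id, "g1")
})
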