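test_that("simulated pseudotimes degenerate to capture times when sigma is 0", {
  sim <- simulate_expression(sim_config(n_cells_per_group = 5, sigma_tau_true = 0,
                                        n_down = 3, n_up = 3, n_flat = 3, seed = 1))
  expect_equal(sim$truth$cell_truth$tau_true, sim$cells$capture_time_h)
})

test_that("dynamic mean curves are monotone by construction", {
  sim <- small_sim(seed = 5)
  gt <- sim$truth$gene_truth
  for (i in which(gt$class == "down")) {
    m0 <- pseudokl:::.gene_mean("down", 0, gt$baseline[i], gt$amplitude[i],
                                gt$center[i], gt$width[i])
    m48 <- pseudokl:::.gene_mean("down", 48, gt$baseline[i], gt$amplitude[i],
                                 gt$center[i], gt$width[i])
    expect_gt(m0, m48)
  }
  for (i in which(gt$class == "up")) {
    m0 <- pseudokl:::.gene_mean("up", 0, gt$baseline[i], gt$amplitude[i],
                                gt$center[i], gt$width[i])
    m48 <- pseudokl:::.gene_mean("up", 48, gt$baseline[i], gt$amplitude[i],
                                 gt$center[i], gt$width[i])
    expect_lt(m0, m48)
  }
})

test_that("fixed seed gives byte-identical simulations; truth is complete", {
  a <- small_sim(seed = 42)
  b <- small_sim(seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_setequal(a$truth$cell_truth$cell_id, colnames(a$counts))
  expect_setequal(a$truth$gene_truth$gene, rownames(a$counts))
  expect_true(all(a$truth$cell_truth$size_factor_true > 0))
  c1 <- small_sim(seed = 43)
  expect_false(identical(a$counts, c1$counts))
})

test_that("degenerate simulation configs error", {
  expect_error(sim_config(n_down = 5, seed = NULL), "seed")
  expect_error(sim_config(n_cells_per_group = 0, seed = 1), "n_cells_per_group")
  expect_error(sim_config(n_down = 0, n_up = 0, n_flat = 0, seed = 1),
               "at least one")
})

test_that("null simulation has no capture-time structure", {
  # per-gene one-way ANOVA across capture groups: at alpha = 0.01 the
  # rejection rate over many genes/seeds stays near nominal
  n_sig <- 0L; n_tot <- 0L
  for (seed in 1:8) {
    sim <- simulate_null_expression(sim_config(n_cells_per_group = 12,
                                               n_down = 0, n_up = 0, n_flat = 25,
                                               seed = seed))
    working <- log_transform_counts(sim$counts)
    grp <- factor(sim$cells$capture_time_h)
    p <- apply(working, 1L, function(y) {
      if (sd(y) == 0) return(1)
      stats::anova(stats::lm(y ~ grp))[["Pr(>F)"]][1L]
    })
    n_sig <- n_sig + sum(p < 0.01); n_tot <- n_tot + length(p)
  }
  expect_gte(1 - n_sig / n_tot, 0.98)
})

test_that("null-data roughness p-values are uniform for data-independent orderings", {
  p <- withr::with_seed(99, vapply(1:200, function(i) {
    sim <- simulate_null_expression(sim_config(n_cells_per_group = 8, n_down = 0,
                                               n_up = 0, n_flat = 20, seed = 5000 + i))
    working <- log_transform_counts(sim$counts)
    tau <- setNames(sample(ncol(working)), colnames(working))
    roughness_permutation_test(working, tau, n_perm = 99)$p_value
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("binding landscape plants recoverable occupancy truth", {
  sim <- simulate_binding_landscape(n_genes = 40, seed = 21)
  calls <- call_osn_occupancy(tss = sim$tss, binding = sim$binding)
  expect_identical(calls$occupied, sim$truth$occupied_true)
  # the one-dataset violation mode never qualifies twice
  one_ds <- sim$truth$gene[sim$truth$mode == "one_dataset"]
  expect_true(all(calls$n_qualifying[calls$gene %in% one_ds] <= 1L))
  # empty landscape: all calls false
  empty <- lapply(sim$binding, function(d) lapply(d, function(f) f[0, , drop = FALSE]))
  calls0 <- call_osn_occupancy(tss = sim$tss, binding = empty)
  expect_false(any(calls0$occupied))
  expect_error(simulate_binding_landscape(n_genes = 5, seed = 1, up_bp = NULL),
               "window")
})
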