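test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 30, seed = 77, scenario = "mixed")
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a, b)
  coh1 <- simulate_cohort(sim_config(n_samples = 15, seed = 5), n_genes = 5)
  coh2 <- simulate_cohort(sim_config(n_samples = 15, seed = 5), n_genes = 5)
  expect_identical(coh1$expr, coh2$expr)
  expect_identical(coh1$truth, coh2$truth)
})

test_that("scenario presets set the signal parameters consistently", {
  expect_equal(sim_config(scenario = "null")$beta1, 0)
  expect_equal(sim_config(scenario = "null")$sigma_Int2, 0)
  expect_equal(sim_config(scenario = "fixed_only")$sigma_Int2, 0)
  expect_gt(sim_config(scenario = "fixed_only")$beta1, 0)
  expect_equal(sim_config(scenario = "interaction_only")$beta1, 0)
  expect_gt(sim_config(scenario = "interaction_only")$sigma_Int2, 0)
  expect_error(sim_config(sigma_e2 = -1), "sigma_e2")
})

test_that("Dirichlet IER compositions sum to one exactly", {
  cfg <- sim_config(n_samples = 40, k_introns = 6, seed = 12)
  sp <- simulate_pair(cfg)
  expect_equal(unname(colSums(sp$ier_block)), rep(1, 40), tolerance = 1e-12)
})

test_that("the random slope has empirical covariance sigma_Int2 * Sigma", {
  sp <- make_instance(n = 15, k = 3, seed = 20)
  K <- sp$kernel
  s2 <- 0.7
  set.seed(123)
  draws <- replicate(5000, splicecor:::rmvn_kernel(K, s2))
  emp <- tcrossprod(draws - rowMeans(draws)) / (ncol(draws) - 1)
  target <- s2 * K$matrix
  # entrywise Monte-Carlo agreement; sd of a covariance entry is
  # O(s2 * max|Sigma| / sqrt(nrep))
  tol <- 6 * s2 * max(abs(K$matrix)) / sqrt(5000)
  expect_lt(max(abs(emp - target)), tol * 3)
})

test_that("interaction-only signal shows the stratified-correlation pattern", {
  cfg <- sim_config(n_samples = 3000, k_introns = 3, seed = 21,
                    sigma_Int2 = 1, sigma_u2 = 0, scenario = "interaction_only")
  sp <- simulate_pair(cfg)
  # correlation of (x, y) differs between samples in the top versus
  # bottom tertile of the intron whose IER loads most on the slope draw
  load <- abs(cor(t(sp$ier_block), sp$truth$beta2))
  intron <- which.max(load)
  ier <- sp$ier_block[intron, ]
  qs <- quantile(ier, c(1 / 3, 2 / 3))
  lo <- ier <= qs[1]; hi <- ier >= qs[2]
  expect_gt(abs(cor(sp$x[hi], sp$y[hi]) - cor(sp$x[lo], sp$y[lo])), 0.05)
})

test_that("cohort truth tables count signal pairs and files round-trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_samples = 15, seed = 31, scenario = "interaction_only")
  coh <- simulate_cohort(cfg, n_genes = 20, signal_fraction = 0.1, dir = dir)
  expect_equal(sum(coh$truth$effect != "none"), ceiling(0.1 * 20 * 19))
  expect_equal(nrow(coh$truth), 20 * 19)

  expr <- load_expression(coh$paths[["expression"]])
  expect_equal(expr, coh$expr, tolerance = 1e-12)
  ier <- load_ier(coh$paths[["ier"]], coh$paths[["gene_map"]])
  expect_equal(ier$values, coh$ier$values, tolerance = 1e-12)
  expect_identical(ier$gene_map[rownames(ier$values)],
                   coh$ier$gene_map[rownames(ier$values)])
  cov <- load_covariates(coh$paths[["covariates"]])
  expect_equal(unname(cov), unname(coh$cov), tolerance = 1e-12)
  manifest <- jsonlite::read_json(coh$paths[["manifest"]])
  expect_equal(manifest$seed, 31)
})

test_that("multi-tissue cohorts place shared and tissue-specific signal", {
  out <- simulate_multitissue(sim_config(n_samples = 15, seed = 8,
                                         scenario = "interaction_only"),
                              n_tissues = 3, tissue_specific_fraction = 0.6,
                              n_genes = 8, signal_fraction = 0.2)
  expect_length(out, 3)
  assign <- attr(out, "assignment")
  expect_true(all(assign$scope %in% c("shared", paste0("tissue", 1:3))))
  shared <- assign$pair[assign$scope == "shared"]
  for (ti in 1:3) {
    truth <- out[[ti]]$truth
    active <- paste(truth$predictor, truth$response)[truth$effect != "none"]
    expect_true(all(shared %in% active))
    spec <- assign$pair[assign$scope == paste0("tissue", ti)]
    expect_true(all(spec %in% active))
    other <- assign$pair[!assign$scope %in% c("shared", paste0("tissue", ti))]
    expect_false(any(other %in% active))
  }
})
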