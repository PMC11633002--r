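test_that("with no random intercept the fit reduces to ordinary least squares", {
  cfg <- sim_config(n_samples = 80, k_introns = 3, seed = 21,
                    sigma_u2 = 0, scenario = "fixed_only")
  sp <- simulate_pair(cfg)
  fit <- fit_null(sp$y, sp$x, sp$Z, sp$kernel)
  ols <- stats::lm.fit(cbind(sp$x, sp$Z), sp$y)
  expect_lt(fit$sigma_u2, 0.05)
  if (fit$sigma_u2 == 0) {
    expect_equal(unname(fit$beta), unname(ols$coefficients),
                 tolerance = 1e-6)
  }
  # nesting: mixed-model ML log-likelihood >= OLS submodel log-likelihood
  n <- length(sp$y)
  s2 <- sum(ols$residuals^2) / n
  ll_ols <- -0.5 * n * (log(2 * pi * s2) + 1)
  expect_gte(fit$loglik, ll_ols - 1e-8)
})

test_that("eigenbasis computations equal dense matrix algebra on small instances", {
  for (seed in 1:3) {
    sp <- make_instance(n = 30, k = 4, seed = seed)
    fit <- fit_null(sp$y, sp$x, sp$Z, sp$kernel)
    V <- fit$sigma_u2 * sp$kernel$matrix + fit$sigma_e2 * diag(30)
    expect_equal(fit$vinv_r, drop(solve(V, fit$residuals)), tolerance = 1e-8)
    # GLS orthogonality of residuals under the V^-1 inner product
    M <- cbind(sp$x, sp$Z)
    expect_lt(max(abs(crossprod(M, fit$vinv_r))), 1e-6)
  }
})

test_that("variance components are recovered on average (n = 500)", {
  su <- se <- numeric(60)
  for (i in seq_len(60)) {
    cfg <- sim_config(n_samples = 500, sigma_u2 = 1, sigma_e2 = 1,
                      seed = 30000 + i, scenario = "null")
    sp <- simulate_pair(cfg)
    fit <- fit_null(sp$y, sp$x, sp$Z, sp$kernel)
    su[i] <- fit$sigma_u2; se[i] <- fit$sigma_e2
  }
  expect_lt(abs(mean(su) - 1), 0.1)
  expect_lt(abs(mean(se) - 1), 0.1)
})

test_that("estimates are invariant to sample reordering", {
  sp <- make_instance(n = 40, k = 3, seed = 8)
  fit <- fit_null(sp$y, sp$x, sp$Z, sp$kernel)
  perm <- sample(40)
  K2 <- build_kernel(sp$ier_block[, perm])
  fit2 <- fit_null(sp$y[perm], sp$x[perm], sp$Z[perm, ], K2)
  expect_equal(fit2$sigma_u2, fit$sigma_u2, tolerance = 1e-6)
  expect_equal(fit2$sigma_e2, fit$sigma_e2, tolerance = 1e-6)
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-6)
})

test_that("collinear predictors are rejected", {
  sp <- make_instance(n = 30, k = 3, seed = 9)
  x_bad <- drop(sp$Z %*% c(1, 0.5, -0.2, 0.1))
  expect_error(fit_null(sp$y, x_bad, sp$Z, sp$kernel),
               class = "splicecor_collinearity_error")
})

test_that("full-model components are recovered within 30% at n = 1000", {
  # 8 introns per predictor gene: the typical splicing richness of an
  # analyzed gene (intron counts in real scans center around 8); at
  # much lower kernel rank the variance-component medians inherit the
  # heavy small-rank skew of ML
  res <- replicate(40, NA_real_, simplify = FALSE)
  sx <- si <- su <- se <- numeric(40)
  for (i in seq_len(40)) {
    cfg <- sim_config(n_samples = 1000, k_introns = 8, seed = 50000 + i,
                      beta1 = sqrt(0.2), sigma_Int2 = 0.3,
                      sigma_u2 = 0.3, sigma_e2 = 1, scenario = "custom")
    sp <- simulate_pair(cfg)
    vc <- fit_full_variance_components(sp$y, sp$x, sp$Z, sp$kernel)
    sx[i] <- vc$sigma_X2; si[i] <- vc$sigma_Int2
    su[i] <- vc$sigma_u2; se[i] <- vc$sigma_e2
  }
  expect_lt(abs(median(sx) / 0.2 - 1), 0.3)
  expect_lt(abs(median(si) / 0.3 - 1), 0.3)
  expect_lt(abs(median(su) / 0.3 - 1), 0.3)
  expect_lt(abs(median(se) / 1.0 - 1), 0.3)
})

test_that("under a null interaction the interaction variance sits at the boundary", {
  v <- numeric(40)
  for (i in seq_len(40)) {
    cfg <- sim_config(n_samples = 500, seed = 40000 + i,
                      scenario = "fixed_only")
    sp <- simulate_pair(cfg)
    v[i] <- fit_full_variance_components(sp$y, sp$x, sp$Z, sp$kernel)$sigma_Int2
  }
  # ML boundary behavior: median exactly at 0, all estimates small
  expect_lte(median(v), 1e-3)
  expect_true(all(v <= 0.05))
})

test_that("a response with no signal puts both signal variances at zero", {
  sp <- make_instance(n = 50, k = 3, seed = 10, scenario = "null",
                      sigma_u2 = 0)
  y <- drop(sp$Z %*% c(0, 0.5, 0.5, 0.5))  # y = Z gamma exactly
  vc <- fit_full_variance_components(y, sp$x, sp$Z, sp$kernel)
  expect_lt(vc$sigma_X2, 1e-8)
  expect_lt(vc$sigma_Int2, 1e-8)
})
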