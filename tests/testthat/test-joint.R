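test_that("Q(rho) matches dense evaluation across the grid on 20-sample instances", {
  for (seed in 1:3) {
    sp <- make_instance(n = 20, k = 3, seed = seed)
    fit0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
    jt <- joint_score(sp$y, sp$x, fit0, sp$kernel)
    for (i in seq_len(nrow(jt$per_rho))) {
      expect_equal(jt$per_rho$Q[i],
                   dense_Q_joint(sp, fit0, jt$per_rho$rho[i]),
                   tolerance = 1e-10)
    }
    expect_gte(jt$p_combined, 0)
    expect_lte(jt$p_combined, 1)
    expect_true(jt$rho_star %in% jt$per_rho$rho)
  }
})

test_that("the rho = 0 leg equals the GLS correlation test given V", {
  for (seed in 1:50) {
    sp <- make_instance(n = 25, k = 3, seed = 100 + seed)
    fit0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
    jt <- joint_score(sp$y, sp$x, fit0, sp$kernel, fixed_rho = 0)
    ct <- correlation_test(sp$y, sp$x, sp$Z, sp$kernel, mode = "gls_kernel")
    expect_equal(jt$per_rho$p[1], ct$p_value, tolerance = 1e-6)
  }
})

test_that("rho_star concentrates at 0 under fixed-only and 1 under interaction-only signal", {
  stars_fixed <- stars_int <- numeric(60)
  for (i in seq_len(60)) {
    cfg <- sim_config(n_samples = 300, k_introns = 5, seed = 80000 + i,
                      beta1 = 0.5, scenario = "fixed_only")
    sp <- simulate_pair(cfg)
    fit0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
    stars_fixed[i] <- joint_score(sp$y, sp$x, fit0, sp$kernel)$rho_star
    cfg <- sim_config(n_samples = 300, k_introns = 5, seed = 90000 + i,
                      scenario = "interaction_only")
    sp <- simulate_pair(cfg)
    fit0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
    stars_int[i] <- joint_score(sp$y, sp$x, fit0, sp$kernel)$rho_star
  }
  expect_gt(mean(stars_fixed <= 0.1), 0.5)
  expect_gt(mean(stars_int >= 0.9), 0.5)
})

test_that("rho estimates recover designed variance partitions", {
  meds <- numeric(3)
  truths <- c(0, 0.75, 1)
  for (ti in seq_along(truths)) {
    t_ <- truths[ti]
    rhos <- numeric(30)
    for (i in seq_len(30)) {
      cfg <- sim_config(n_samples = 500, seed = 110000 + 1000 * ti + i,
                        beta1 = sqrt((1 - t_) * 0.4),
                        sigma_Int2 = t_ * 0.4, scenario = "custom")
      sp <- simulate_pair(cfg)
      rhos[i] <- estimate_rho(sp$y, sp$x, sp$Z, sp$kernel)$rho_hat
    }
    meds[ti] <- median(rhos)
  }
  expect_lte(meds[1], 0.05)          # sigma_Int2 = 0 truth
  expect_gt(meds[2], 0.6)            # 3:1 interaction:fixed (truth 0.75)
  expect_lt(meds[2], 0.9)
  expect_gte(meds[3], 0.9)           # pure interaction
})

test_that("correlation test matches the closed-form t statistic and calibrates", {
  # textbook 10-point instance, hand-computed partial t statistic
  x <- c(1.2, -0.4, 0.8, 2.1, -1.5, 0.3, -0.9, 1.7, 0.5, -1.1)
  z <- c(0.5, 1.0, -0.2, 0.8, -1.1, 0.0, 0.4, -0.6, 1.2, -0.3)
  y <- 0.7 * x + 0.4 * z + c(0.1, -0.2, 0.3, -0.1, 0.2, -0.3, 0.1, 0.05,
                             -0.15, 0.25)
  Z <- cbind(1, z)
  M <- cbind(x, Z)
  b <- solve(crossprod(M), crossprod(M, y))
  r <- y - M %*% b
  s2 <- sum(r^2) / (10 - 3)
  tref <- b[1] / sqrt(s2 * solve(crossprod(M))[1, 1])
  ct <- correlation_test(y, x, Z, mode = "ols")
  expect_equal(ct$statistic, drop(tref), tolerance = 1e-10)
  expect_equal(ct$p_value, 2 * pt(abs(tref), 7, lower.tail = FALSE),
               tolerance = 1e-12)

  # null calibration
  set.seed(31)
  pnull <- replicate(400, {
    n <- 50
    x <- rnorm(n); Z <- cbind(1, rnorm(n))
    y <- 0.3 * Z[, 2] + rnorm(n)
    correlation_test(y, x, Z, mode = "ols")$p_value
  })
  expect_gt(mean(pnull <= 0.05), 0.02)
  expect_lt(mean(pnull <= 0.05), 0.08)
})

test_that("with no random intercept the GLS mode reduces to the OLS score test", {
  cfg <- sim_config(n_samples = 100, k_introns = 3, seed = 15,
                    sigma_u2 = 0, scenario = "fixed_only")
  sp <- simulate_pair(cfg)
  fit0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
  expect_identical(fit0$sigma_u2, 0)   # boundary estimate at this seed
  ct_gls <- correlation_test(sp$y, sp$x, sp$Z, sp$kernel, mode = "gls_kernel")
  ct_ols <- correlation_test(sp$y, sp$x, sp$Z, mode = "ols",
                             reference = "chisq")
  expect_equal(ct_gls$p_value, ct_ols$p_value, tolerance = 1e-10)
})
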