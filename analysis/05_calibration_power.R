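#!/usr/bin/env Rscript
# Step 5: a compact operating-characteristics study of the three tests:
# type-I error under the null and power under interaction-only signal
# (n = 300 samples, 5 introns, 300 replicates each), plus a
# differential-correlation calibration check. Replicate counts here are
# chosen for a quick desk run; scripts/acceptance.R repeats the
# calibration at larger replicate counts.

suppressMessages(library(splicecor))
seed <- 20260927L
nrep <- 300

run_cells <- function(scenario, seed0) {
  p <- matrix(NA_real_, nrep, 3,
              dimnames = list(NULL, c("interaction", "joint", "correlation")))
  for (i in seq_len(nrep)) {
    cfg <- sim_config(n_samples = 300, k_introns = 5, seed = seed0 + i,
                      scenario = scenario)
    sp <- simulate_pair(cfg)
    nf <- fit_null(sp$y, sp$x, sp$Z, sp$kernel)
    p[i, 1] <- interaction_score(sp$y, sp$x, nf, sp$kernel)$p_value
    nf0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
    p[i, 2] <- joint_score(sp$y, sp$x, nf0, sp$kernel)$p_combined
    p[i, 3] <- correlation_test(sp$y, sp$x, sp$Z, sp$kernel,
                                mode = "gls_kernel")$p_value
  }
  colMeans(p <= 0.05)
}

null_rates <- run_cells("null", seed)
power_rates <- run_cells("interaction_only", seed + nrep)
out <- data.frame(test = names(null_rates),
                  type1_error = unname(null_rates),
                  power_interaction_only = unname(power_rates))
utils::write.table(out, "results/calibration.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("rejection rates at alpha = 0.05:")
for (i in seq_len(nrow(out)))
  message(sprintf("  %-11s type-I %.3f | power %.3f", out$test[i],
                  out$type1_error[i], out$power_interaction_only[i]))

set.seed(seed)
p_dc <- replicate(500, {
  n <- 100; x <- rnorm(2 * n); g <- rep(0:1, each = n); Z <- cbind(rnorm(2 * n))
  y <- 0.5 * x + 0.3 * Z[, 1] + rnorm(2 * n)
  differential_correlation(y, x, Z, g)$p_value
})
message(sprintf("differential-correlation null rejection at 0.05: %.3f",
                mean(p_dc <= 0.05)))
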