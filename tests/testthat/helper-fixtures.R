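# Fixtures are built in code at test time; nothing is stored on disk.

# Small expression fixture written as TSV or GCT.
write_expr_fixture <- function(path, dialect = "tsv",
                               genes = c("GA", "GB", "GC"),
                               samples = c("S1", "S2", "S3", "S4"),
                               values = NULL) {
  if (is.null(values))
    values <- matrix(seq_len(length(genes) * length(samples)) / 7,
                     length(genes), length(samples),
                     dimnames = list(genes, samples))
  write_expression(values, path, dialect = dialect)
  values
}

# Two-cluster IER fixture with count/total entries; returns the expected
# numeric matrix.
write_ier_fixture <- function(path, map_path) {
  ids <- c("chr1:10:20:cluA", "chr1:10:30:cluA",
           "chr2:5:15:cluB", "chr2:5:25:cluB", "chr2:5:35:cluB")
  tab <- data.frame(
    intron = ids,
    S1 = c("3/12", "9/12", "0.2", "0.3", "0.5"),
    S2 = c("0.5", "0.5", "1/4", "1/4", "2/4"),
    S3 = c("0/0", "0/0", "0.1", "0.2", "0.7"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(ids, c("GA", "GA", "GB", "GB", "GB")),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  expected <- rbind(c(0.25, 0.5, NA), c(0.75, 0.5, NA),
                    c(0.2, 0.25, 0.1), c(0.3, 0.25, 0.2), c(0.5, 0.5, 0.7))
  dimnames(expected) <- list(ids, c("S1", "S2", "S3"))
  expected
}

# Simulated (y, x, Z, kernel) instance for direct test-statistic checks.
make_instance <- function(n = 20, k = 3, seed = 1, scenario = "mixed", ...) {
  cfg <- sim_config(n_samples = n, k_introns = k, seed = seed,
                    scenario = scenario, ...)
  simulate_pair(cfg)
}

# Dense (literal, n x n) evaluation of the interaction statistic
# Q = r' V^-1 diag(x) Sigma diag(x) V^-1 r.
dense_Q_interaction <- function(sp, fit) {
  V <- fit$sigma_u2 * sp$kernel$matrix + fit$sigma_e2 * diag(sp$kernel$n)
  r <- fit$residuals
  D <- diag(sp$x)
  drop(t(r) %*% solve(V) %*% D %*% sp$kernel$matrix %*% D %*% solve(V) %*% r)
}

# Dense evaluation of the joint statistic at a given rho.
dense_Q_joint <- function(sp, fit0, rho) {
  n <- sp$kernel$n
  V <- fit0$sigma_u2 * sp$kernel$matrix + fit0$sigma_e2 * diag(n)
  Krho <- (1 - rho) * matrix(1, n, n) + rho * sp$kernel$matrix
  r <- fit0$residuals
  D <- diag(sp$x)
  drop(t(r) %*% solve(V) %*% D %*% Krho %*% D %*% solve(V) %*% r)
}

# Monte-Carlo tail probability of a chi-square mixture.
mc_mixture_tail <- function(Q, w, ndraw = 2e5, seed = 99) {
  set.seed(seed)
  draws <- colSums(w * matrix(stats::rchisq(length(w) * ndraw, df = 1),
                              length(w)))
  mean(draws >= Q)
}
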