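# Genome-scan bookkeeping: pair enumeration, Bonferroni, BH FDR,
# stratified FDR, and Storey's pi0 (non-null proportion) estimate.

#' Number of ordered (directed) gene pairs
#'
#' @param n_genes number of genes (>= 2).
#' @return \code{n_genes * (n_genes - 1)}.
#' @examples count_pairs(3223)  # 10384506
#' @export
count_pairs <- function(n_genes) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 2)
    stop_splicecor("n_genes must be >= 2", class = "splicecor_domain_error")
  n_genes * (n_genes - 1)
}

#' Bonferroni p-value threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests.
#' @return \code{alpha / m}.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH at level \code{q}; missing p-values are excluded from the
#' procedure and rejected = NA in the mask.
#'
#' @param p_values numeric vector in [0, 1] (NAs allowed).
#' @param q FDR level.
#' @return list with \code{rejected} (logical mask, same length as input)
#'   and \code{adjusted} (BH-adjusted p-values).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(list(rejected = logical(0), adjusted = numeric(0)))
  assert_prob(p_values, "p_values")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, adjusted = adj)
}

#' Stratified FDR control
#'
#' Applies BH independently within each stratum at level \code{q}. The
#' default stratification in genome scans is by response gene (many
#' predictors tested against each response), which adapts the threshold
#' to per-response signal density.
#'
#' @param p_values numeric vector.
#' @param strata vector of stratum labels, same length.
#' @param q FDR level.
#' @return logical rejection mask (NA where p is NA).
#' @export
stratified_fdr <- function(p_values, strata, q = 0.05) {
  stopifnot(length(p_values) == length(strata))
  rejected <- rep(NA, length(p_values))
  for (s in unique(strata)) {
    idx <- which(strata == s & !is.na(p_values))
    if (!length(idx)) next
    rejected[idx] <- bh_fdr(p_values[idx], q)$rejected
  }
  rejected[is.na(p_values)] <- NA
  as.logical(rejected)
}

#' Storey's estimate of the null proportion pi0
#'
#' The lambda-average estimator: \eqn{\hat\pi_0(\lambda) =
#' \#\{p > \lambda\} / (m(1-\lambda))} averaged over the lambda grid and
#' clipped to [0, 1]. The non-null proportion is \eqn{1 - \hat\pi_0}.
#' The averaging variant (rather than the spline smoother) is used for
#' determinism.
#'
#' @param p_values numeric vector of p-values.
#' @param lambda_grid tuning grid (default 0.05, 0.10, ..., 0.95).
#' @return estimated pi0 in [0, 1].
#' @export
storey_pi0 <- function(p_values, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  p <- p_values[!is.na(p_values)]
  assert_prob(p, "p_values")
  if (length(p) < 100)
    warn_splicecor("pi0 estimate unstable with %d p-values", length(p))
  est <- vapply(lambda_grid,
                function(l) mean(p > l) / (1 - l), 0)
  min(max(mean(est), 0), 1)
}

#' Write / read a pair-result table
#'
#' Fixed, documented column order: predictor, response, followed by the
#' computed statistic columns. Gzip-transparent (a \code{.gz} suffix
#' compresses on write and decompresses on read).
#'
#' @param pair_table data.frame keyed by (predictor, response).
#' @param path TSV path.
#' @export
write_pair_table <- function(pair_table, path) {
  lead <- intersect(c("predictor", "response"), names(pair_table))
  pair_table <- pair_table[, c(lead, setdiff(names(pair_table), lead)),
                           drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(pair_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
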