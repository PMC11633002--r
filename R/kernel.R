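# Splicing kernel: sample-sample covariance of a gene's isoform composition.
#
# The kernel is the Gram matrix of the standardized intron-excision-ratio
# (IER) profile of one gene: samples with similar isoform composition get
# large entries, and the random slope / random intercept of the mixed model
# are assumed to have covariance proportional to it.

#' Build a splicing sample-similarity kernel from a gene's IER block
#'
#' Takes the intron x sample matrix of intron-excision ratios of one gene,
#' standardizes each intron across samples (mean 0, unit variance; constant
#' introns are dropped with a warning), and forms
#' \deqn{\Sigma = \tilde{W}\tilde{W}^\top / k,}
#' where \eqn{\tilde{W}} is the sample x intron standardized matrix and
#' \eqn{k} the number of surviving introns, then rescales \eqn{\Sigma} so
#' that \eqn{\mathrm{trace}(\Sigma) = n}. The trace normalization makes the
#' variance-component scale comparable across predictor genes with
#' different intron counts.
#'
#' The nonzero eigenpairs are computed once (via the thin SVD of
#' \eqn{\tilde{W}}, so no \eqn{n^3} work is done) and cached on the
#' returned object; eigenvalues below \code{1e-8} times the largest are
#' truncated to exactly 0 and dropped. Within-cluster IERs are linearly
#' dependent (they sum to 1 per sample); the Gram construction tolerates
#' the implied rank deficiency, so no intron is dropped on that account.
#'
#' @param ier_block numeric matrix, introns in rows, samples in columns;
#'   no missing values (impute before calling, see
#'   \code{\link{center_and_align}}).
#' @param standardize logical; if \code{FALSE} introns are only centered,
#'   not scaled (raw-covariance mode for sensitivity analysis).
#' @return an object of class \code{sample_kernel}: a list with elements
#'   \code{matrix} (n x n), \code{evalues} (nonzero eigenvalues,
#'   descending), \code{evectors} (orthonormal n x r), \code{n},
#'   \code{k_introns} (introns used), \code{dropped} (constant introns
#'   removed).
#' @examples
#' ier <- matrix(runif(5 * 20), 5, 20)
#' ier <- sweep(ier, 2, colSums(ier), "/")  # compositional columns
#' K <- build_kernel(ier)
#' sum(diag(K$matrix))  # == ncol(ier)
#' @export
build_kernel <- function(ier_block, standardize = TRUE) {
  if (!is.matrix(ier_block)) ier_block <- as.matrix(ier_block)
  if (nrow(ier_block) < 2)
    stop_splicecor("need at least 2 introns, got %d", nrow(ier_block),
                   class = "splicecor_kernel_error")
  n <- ncol(ier_block)
  if (n < 10)
    stop_splicecor("need at least 10 samples, got %d", n,
                   class = "splicecor_kernel_error")
  if (anyNA(ier_block) || !all(is.finite(ier_block)))
    stop_splicecor("IER block contains missing or non-finite values",
                   class = "splicecor_kernel_error")

  W <- t(ier_block)                      # sample x intron
  mu <- colMeans(W)
  W <- sweep(W, 2, mu, "-")
  sdv <- sqrt(colSums(W^2) / (n - 1))
  keep <- sdv > 1e-12
  dropped <- colnames(W)[!keep] %||% which(!keep)
  if (!any(keep))
    stop_splicecor("degenerate kernel: all introns have zero variance",
                   class = "splicecor_degenerate_kernel")
  if (sum(keep) < 2)
    warn_splicecor("only %d intron with variance survives; kernel has rank 1",
                   sum(keep))
  W <- W[, keep, drop = FALSE]
  if (standardize) W <- sweep(W, 2, sdv[keep], "/")
  k <- ncol(W)

  sv <- svd(W, nu = min(n, k), nv = 0)
  ev <- sv$d^2 / k
  tr <- sum(ev)                          # trace(W W^T / k)
  scale <- n / tr
  ev <- ev * scale
  ev <- truncate_eigenvalues(ev)
  pos <- ev > 0
  ev <- ev[pos]
  U <- sv$u[, pos, drop = FALSE]
  rownames(U) <- colnames(ier_block)
  Sigma <- U %*% (ev * t(U))
  dimnames(Sigma) <- list(colnames(ier_block), colnames(ier_block))

  structure(list(matrix = Sigma, evalues = ev, evectors = U,
                 n = n, k_introns = k, dropped = dropped),
            class = "sample_kernel")
}

#' Sample-similarity kernel from an arbitrary covariate set
#'
#' Generalization of \code{\link{build_kernel}} to any set of sample-level
#' covariates suspected to drive inter-sample variation in effects (the
#' number of covariates may far exceed the sample size: the Gram matrix is
#' n x n regardless). Identical contract and implementation.
#'
#' @inheritParams build_kernel
#' @param covariate_block numeric matrix, covariates in rows, samples in
#'   columns.
#' @return a \code{sample_kernel}; see \code{\link{build_kernel}}.
#' @export
kernel_from_covariates <- function(covariate_block, standardize = TRUE) {
  build_kernel(covariate_block, standardize = standardize)
}

#' @export
print.sample_kernel <- function(x, ...) {
  cat(sprintf("sample_kernel: %d samples, %d introns/covariates, rank %d\n",
              x$n, x$k_introns, length(x$evalues)))
  cat(sprintf("  top eigenvalues: %s\n",
              paste(signif(utils::head(x$evalues, 5), 4), collapse = ", ")))
  invisible(x)
}
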