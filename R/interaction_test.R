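# Variance-component score test for splicing-induced inter-sample
# variation in the expression-expression slope ("interaction test"):
# H0: sigma_Int^2 = 0 in the mixed model with random slope covariance
# sigma_Int^2 * diag(x) Sigma diag(x).

# Null mixture weights of a quadratic score statistic r' V^-1 K V^-1 r
# with K = B B', computed in the projected (SKAT-family) form
# eig(B' P B), P = V^-1 - V^-1 M (M'V^-1M)^-1 M'V^-1.
projected_weights <- function(fit, B) {
  VB <- fit$vinv(B)
  VM <- fit$vinv(fit$M)
  BtVB <- crossprod(B, VB)
  BtVM <- crossprod(B, VM)
  MtVM <- crossprod(fit$M, VM)
  W <- BtVB - BtVM %*% solve(MtVM, t(BtVM))
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sort(truncate_eigenvalues(ev), decreasing = TRUE)
}

#' Score test for TE-splicing interaction (random slope) effects
#'
#' Tests \eqn{H_0: \sigma_{Int}^2 = 0} with the quadratic score statistic
#' \deqn{Q = (y-\hat y)^\top V^{-1}\mathrm{diag}(x)\,\Sigma\,
#'   \mathrm{diag}(x)V^{-1}(y-\hat y),}
#' where \eqn{\hat y} and \eqn{V = \hat\sigma_u^2\Sigma + \hat\sigma_e^2 I}
#' come from the ML null fit. Under the null Q is a weighted sum of 1-df
#' chi-squares; by default the weights are the eigenvalues of the
#' projected matrix \eqn{B^\top P B} with
#' \eqn{\mathrm{diag}(x)\Sigma\,\mathrm{diag}(x) = BB^\top} and P the
#' covariance-adjusted residual projection (this is the form that
#' calibrates; \code{weights = "kernel_only"} exposes the plain
#' eigenvalues of \eqn{\Sigma} for comparison).
#'
#' @param y response gene expression (mean-centered).
#' @param x predictor gene expression (mean-centered).
#' @param null_fit \code{lmm_fit} from \code{\link{fit_null}} on the same
#'   \code{(y, x, Z, kernel)}.
#' @param kernel the predictor gene's \code{sample_kernel}.
#' @param weights \code{"projected"} (default) or \code{"kernel_only"}.
#' @param method p-value method: \code{"auto"} (Liu, switching to exact
#'   inversion below 1e-4), \code{"liu"}, or \code{"davies"}.
#' @return list of class \code{splice_test} with \code{Q}, \code{p_value},
#'   \code{weights_used}, \code{df_effective} (Liu moment-matching df),
#'   \code{method}, \code{degenerate} flag.
#' @export
interaction_score <- function(y, x, null_fit, kernel,
                              weights = c("projected", "kernel_only"),
                              method = c("auto", "liu", "davies")) {
  weights <- match.arg(weights)
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  U <- kernel$evectors
  lam <- kernel$evalues

  degenerate_result <- function() {
    structure(list(Q = 0, p_value = 1, weights_used = numeric(0),
                   df_effective = NA_real_, method = method,
                   degenerate = TRUE), class = "splice_test")
  }
  if (all(x == 0)) return(degenerate_result())

  s <- x * null_fit$vinv_r                # diag(x) V^-1 r
  Q <- sum(lam * drop(crossprod(U, s))^2) # s' Sigma s

  B <- (U * rep(sqrt(lam), each = n)) * x # diag(x) U L^1/2
  lambda <- switch(weights,
                   projected = projected_weights(null_fit, B),
                   kernel_only = lam)
  if (!length(lambda) || all(lambda == 0)) return(degenerate_result())

  p <- mixture_pvalue(Q, lambda, method)
  df_eff <- sum(lambda)^2 / sum(lambda^2)
  structure(list(Q = Q, p_value = as.numeric(p), weights_used = lambda,
                 df_effective = df_eff, method = method, degenerate = FALSE),
            class = "splice_test")
}

#' @export
print.splice_test <- function(x, ...) {
  cat(sprintf("splice_test: Q = %.4g, p = %.3g%s\n", x$Q, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}
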