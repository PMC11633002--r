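# Joint association test for fixed (expression-expression) plus random
# (splicing-interaction) slope, the variance-partition estimate rho, and
# the standard correlation-test baseline.

#' Joint association test for fixed and random slope
#'
#' Tests the combined effect of the predictor gene: its overall slope and
#' its splicing-induced random slope. The model is rewritten so both live
#' in one variance component with kernel
#' \eqn{K(\rho) = (1-\rho)\,\mathbf{1}\mathbf{1}^\top + \rho\,\Sigma},
#' where \eqn{\rho} is the proportion of the predictor's contribution
#' attributable to the random (interaction) part. The null model contains
#' the covariates and random intercept only (the predictor is excluded
#' entirely). For each \eqn{\rho} on a grid,
#' \deqn{Q(\rho) = (y-\hat y)^\top V^{-1}\mathrm{diag}(x) K(\rho)
#'   \mathrm{diag}(x) V^{-1}(y-\hat y)}
#' is referred to its projected mixture-of-chi-square null, and the grid
#' p-values are aggregated by the Cauchy combination, which is valid
#' under their dependence. At \eqn{\rho = 0} the test reduces to the
#' generalized-least-squares test of the predictor's slope given
#' covariance V, i.e. the standard correlation test adjusting for
#' covariates and splicing (see \code{\link{correlation_test}}).
#'
#' @param y response gene expression (mean-centered).
#' @param x predictor gene expression (mean-centered).
#' @param null_fit_assoc \code{lmm_fit} from
#'   \code{fit_null(y, NULL, Z, kernel)}: covariates + random intercept
#'   only.
#' @param kernel the predictor gene's \code{sample_kernel}.
#' @param rho_grid grid of variance-partition values in [0, 1].
#' @param method p-value method for each rho leg; the default is the
#'   exact mixture tail (\code{\link{davies_pvalue}}): the Cauchy
#'   combination is sensitive to body accuracy of every leg, and the
#'   moment-matched approximation is visibly non-uniform at
#'   intermediate rho where one mixture weight dominates.
#' @param fixed_rho optional single rho; skips the grid and returns the
#'   p-value at that rho only.
#' @return list of class \code{joint_test} with \code{p_combined},
#'   \code{per_rho} (data.frame rho / Q / p), \code{rho_star} (grid argmin
#'   of p), \code{degenerate}.
#' @export
joint_score <- function(y, x, null_fit_assoc, kernel,
                        rho_grid = seq(0, 1, by = 0.1),
                        method = c("davies", "auto", "liu"),
                        fixed_rho = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (!is.null(fixed_rho)) rho_grid <- fixed_rho
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1))

  if (all(x == 0)) {
    return(structure(list(p_combined = 1,
                          per_rho = data.frame(rho = rho_grid, Q = 0, p = 1),
                          rho_star = rho_grid[1L], degenerate = TRUE),
                     class = "joint_test"))
  }

  U <- kernel$evectors
  lam <- kernel$evalues
  fit <- null_fit_assoc
  s <- x * fit$vinv_r
  q_fixed <- sum(s)^2                      # s' x x^T ... (diag(x) 1 = x)
  q_kern <- sum(lam * drop(crossprod(U, s))^2)

  # unscaled half-kernel blocks: B1 = x (fixed part), Bk = diag(x) U L^1/2
  Bk <- (U * rep(sqrt(lam), each = n)) * x
  Ball <- cbind(x, Bk)
  VB <- fit$vinv(Ball)
  VM <- fit$vinv(fit$M)
  BtVB <- crossprod(Ball, VB)
  BtVM <- crossprod(Ball, VM)
  MtVM <- crossprod(fit$M, VM)
  C <- BtVB - BtVM %*% solve(MtVM, t(BtVM))  # B' P B, unscaled blocks
  C <- (C + t(C)) / 2

  r1 <- 1L
  per <- lapply(rho_grid, function(rho) {
    Q <- (1 - rho) * q_fixed + rho * q_kern
    sc <- c(sqrt(1 - rho), rep(sqrt(rho), ncol(Bk)))
    Crho <- C * (sc %o% sc)
    ev <- eigen(Crho, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(truncate_eigenvalues(pmax(ev, 0)), decreasing = TRUE)
    p <- if (!length(ev) || all(ev == 0)) 1 else mixture_pvalue(Q, ev, method)
    c(Q = Q, p = as.numeric(p))
  })
  per <- do.call(rbind, per)
  per_rho <- data.frame(rho = rho_grid, Q = per[, "Q"], p = per[, "p"])
  p_comb <- if (length(rho_grid) == 1L) per_rho$p else cauchy_combine(per_rho$p)
  structure(list(p_combined = p_comb, per_rho = per_rho,
                 rho_star = rho_grid[which.min(per_rho$p)],
                 degenerate = FALSE),
            class = "joint_test")
}

#' @export
print.joint_test <- function(x, ...) {
  cat(sprintf("joint_test: p_combined = %.3g, rho_star = %.2f\n",
              x$p_combined, x$rho_star))
  invisible(x)
}

#' Estimate the splicing-induced share of a predictor's contribution
#'
#' \eqn{\hat\rho = \hat\sigma_{Int}^2 / (\hat\sigma_{Int}^2 +
#' \hat\sigma_X^2)} from the full-model ML fit
#' (\code{\link{fit_full_variance_components}}): the proportion of the
#' predictor gene's total contribution to the response's variance that is
#' attributable to splicing-induced inter-sample variation rather than
#' the overall slope. Defined as 0 (and flagged degenerate) when both
#' components are estimated at the zero boundary.
#'
#' @inheritParams fit_null
#' @return list of class \code{rho_estimate}: \code{rho_hat},
#'   \code{sigma_X2}, \code{sigma_Int2}, \code{total_sigma2},
#'   \code{degenerate}, \code{converged}.
#' @export
estimate_rho <- function(y, x, Z, kernel) {
  vc <- fit_full_variance_components(y, x, Z, kernel)
  tot <- vc$sigma_X2 + vc$sigma_Int2
  degenerate <- !isTRUE(vc$converged) || is.na(tot) || tot <= 0
  rho <- if (degenerate) 0 else vc$sigma_Int2 / tot
  structure(list(rho_hat = rho, sigma_X2 = vc$sigma_X2,
                 sigma_Int2 = vc$sigma_Int2, total_sigma2 = tot,
                 degenerate = degenerate, converged = vc$converged),
            class = "rho_estimate")
}

#' Standard correlation test of the predictor's slope
#'
#' The main-effects-only baseline: a test of the predictor coefficient in
#' \eqn{y \sim x + Z}. \code{mode = "ols"} is the classical two-sided
#' t-test. \code{mode = "gls_kernel"} additionally adjusts for splicing
#' by including the kernel-structured random intercept: the covariance
#' \eqn{V = \hat\sigma_u^2\Sigma + \hat\sigma_e^2 I} is estimated by ML
#' under the covariate-only null and the slope is tested by the
#' generalized-least-squares score/Wald statistic given that V
#' (chi-square reference), which makes it exactly the \eqn{\rho = 0} leg
#' of the joint test. \code{reference} switches the reference
#' distribution; \code{"chisq"} for both modes makes them coincide when
#' \eqn{\hat\sigma_u^2 = 0}.
#'
#' @inheritParams fit_null
#' @param mode \code{"ols"} or \code{"gls_kernel"}.
#' @param reference \code{"t"} (default for ols) or \code{"chisq"}
#'   (default for gls_kernel).
#' @return list of class \code{splice_test} with \code{statistic} (t or
#'   chi-square), \code{estimate} (slope), \code{p_value}.
#' @export
correlation_test <- function(y, x, Z, kernel = NULL,
                             mode = c("ols", "gls_kernel"),
                             reference = NULL) {
  mode <- match.arg(mode)
  y <- as.numeric(y); x <- as.numeric(x)
  Z <- as.matrix(Z)
  n <- length(y)
  qz <- qr(Z)
  if (sum(qr.resid(qz, x)^2) <= 1e-10 * sum(x^2))
    stop_splicecor("predictor x is collinear with covariates Z",
                   class = "splicecor_collinearity_error")

  if (mode == "ols") {
    reference <- reference %||% "t"
    M <- cbind(x = x, Z)
    fit <- stats::lm.fit(M, y)
    p_ <- ncol(M)
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(M)))
    if (reference == "t") {
      s2 <- rss / (n - p_)
      tval <- fit$coefficients[1L] / sqrt(s2 * XtXinv[1L, 1L])
      p <- 2 * stats::pt(abs(tval), df = n - p_, lower.tail = FALSE)
      stat <- unname(tval)
    } else {
      # score form with the covariate-only null variance (ML scale):
      # literally the gls_kernel computation with V proportional to I
      r0 <- qr.resid(qz, y)
      s2 <- sum(r0^2) / n
      xres <- qr.resid(qz, x)
      stat <- sum(x * r0)^2 / (s2 * sum(xres^2))
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
    est <- unname(fit$coefficients[1L])
  } else {
    if (is.null(kernel))
      stop_splicecor("mode = 'gls_kernel' requires a kernel",
                     class = "splicecor_domain_error")
    reference <- reference %||% "chisq"
    fit0 <- fit_null(y, NULL, Z, kernel)           # covariate-only null
    # GLS score test of the slope given V from the null fit; by the
    # partial-regression identity this equals the Wald test of the slope
    # in the GLS fit of y ~ x + Z with that fixed V.
    u_ <- sum(x * fit0$vinv_r)
    Vx <- fit0$vinv(x)
    VM <- fit0$vinv(fit0$M)
    xPx <- sum(x * Vx) -
      drop(crossprod(crossprod(VM, x), solve(crossprod(fit0$M, VM),
                                             crossprod(VM, x))))
    stat <- u_^2 / xPx
    est <- u_ / xPx
    if (reference == "t") {
      p <- 2 * stats::pt(sqrt(stat), df = n - ncol(fit0$M) - 1,
                         lower.tail = FALSE)
    } else {
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(statistic = stat, estimate = est, p_value = unname(p),
                 mode = mode, reference = reference, degenerate = FALSE),
            class = "splice_test")
}
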