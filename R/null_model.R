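# Maximum-likelihood fits of the linear mixed model
#
#   y = x b1 + Z g + u + e,   u ~ N(0, s_u^2 Sigma),  e ~ N(0, s_e^2 I),
#
# i.e. the model under the null of no random slope. With Sigma = U L U^T
# (rank r), V = s_e^2 (I + d U L U^T), d = s_u^2 / s_e^2, and every
# quantity the likelihood needs reduces to products with the n x r
# eigenvector block: no n x n solve is ever formed. The variance ratio d
# is profiled by 1-D optimization on the log scale; fixed effects are GLS
# at each d and s_e^2 has a closed form.

# Workhorse: ML/REML fit of y ~ M (fixed) + kernel random intercept.
fit_lmm <- function(y, M, kernel, reml = FALSE,
                    delta_range = c(1e-6, 1e6), tol = 1e-8) {
  n <- length(y)
  U <- kernel$evectors
  lam <- kernel$evalues
  p <- ncol(M)

  Uty <- crossprod(U, y)          # r x 1
  UtM <- crossprod(U, M)          # r x p
  MtM <- crossprod(M)
  Mty <- crossprod(M, y)
  yty <- sum(y^2)

  profile <- function(delta) {
    g <- delta * lam / (1 + delta * lam)
    A <- MtM - crossprod(UtM, g * UtM)        # M' Vbar^-1 M
    b <- Mty - crossprod(UtM, g * Uty)        # M' Vbar^-1 y
    q <- yty - sum(g * Uty^2)                 # y' Vbar^-1 y
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))
    rss <- q - sum(beta * b)
    rss <- max(rss, 0)
    ldet <- sum(log1p(delta * lam))
    if (reml) {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + ldet +
                      determinant(A, logarithm = TRUE)$modulus + (n - p))
    } else {
      s2 <- rss / n
      if (s2 <= 0) s2 <- 1e-300
      ll <- -0.5 * (n * log(2 * pi * s2) + ldet + n)
    }
    list(ll = as.numeric(ll), beta = beta, s2 = s2, g = g)
  }

  opt <- stats::optimize(function(ld) profile(exp(ld))$ll,
                         lower = log(delta_range[1]),
                         upper = log(delta_range[2]),
                         maximum = TRUE, tol = tol)
  cand <- c(0, exp(opt$maximum))
  lls <- vapply(cand, function(d) profile(d)$ll, 0)
  delta <- cand[which.max(lls)]
  fit <- profile(delta)
  if (!is.finite(fit$ll))
    stop_splicecor("non-finite likelihood in mixed-model fit (delta = %g)",
                   delta, class = "splicecor_optim_error")

  beta <- drop(fit$beta)
  names(beta) <- colnames(M)
  fitted <- drop(M %*% fit$beta)
  r <- y - fitted
  sigma_e2 <- fit$s2
  sigma_u2 <- delta * sigma_e2
  g <- fit$g
  # V^-1 r without forming V: (r - U g U'r) / s_e^2
  vinv <- function(v) {
    v <- as.matrix(v)
    (v - U %*% (g * crossprod(U, v))) / sigma_e2
  }

  structure(list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, delta = delta,
                 beta = beta, fitted = fitted, residuals = r,
                 vinv = vinv, vinv_r = drop(vinv(r)),
                 loglik = fit$ll, reml = reml, n = n, M = M,
                 kernel = kernel),
            class = "lmm_fit")
}

#' Fit the null mixed model (no random slope) by maximum likelihood
#'
#' Fits \eqn{y = x\beta_1 + Z\gamma + u + \varepsilon} with
#' \eqn{u \sim N(0, \sigma_u^2 \Sigma)} and
#' \eqn{\varepsilon \sim N(0, \sigma_e^2 I)}. The variance ratio
#' \eqn{\delta = \sigma_u^2/\sigma_e^2} is profiled on a log scale over
#' \code{[1e-6, 1e6]} (with the exact boundary \eqn{\delta = 0} also
#' evaluated, so data without a random intercept reduce to OLS); fixed
#' effects are generalized least squares at the optimum. ML is the
#' default, matching how the score-test covariance
#' \eqn{V = \hat\sigma_u^2\Sigma + \hat\sigma_e^2 I} is defined; REML is
#' available for sensitivity checks.
#'
#' @param y numeric response vector (mean-centered expression of the
#'   response gene).
#' @param x numeric predictor vector (mean-centered expression of the
#'   putative regulator gene), or \code{NULL} to fit the covariate-only
#'   null used by the joint association test.
#' @param Z covariate design matrix including an intercept column.
#' @param kernel \code{sample_kernel} of the predictor gene.
#' @param reml logical; REML instead of ML.
#' @return object of class \code{lmm_fit} with elements \code{sigma_u2},
#'   \code{sigma_e2}, \code{beta1_hat}, \code{gamma_hat},
#'   \code{residuals}, \code{vinv} (a function applying \eqn{V^{-1}}),
#'   \code{vinv_r}, \code{loglik}.
#' @export
fit_null <- function(y, x, Z, kernel, reml = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (!is.null(x)) {
    x <- as.numeric(x)
    stopifnot(length(x) == n)
    # collinearity of x with Z
    qz <- qr(Z)
    rx <- qr.resid(qz, x)
    if (sum(rx^2) <= 1e-10 * sum(x^2))
      stop_splicecor("predictor x is collinear with covariates Z",
                     class = "splicecor_collinearity_error")
    M <- cbind(x = x, Z)
  } else {
    M <- as.matrix(Z)
  }
  fit <- fit_lmm(y, M, kernel, reml = reml)
  fit$beta1_hat <- if (!is.null(x)) unname(fit$beta[1L]) else NA_real_
  fit$gamma_hat <- if (!is.null(x)) fit$beta[-1L] else fit$beta
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: n = %d, sigma_u2 = %.4g, sigma_e2 = %.4g, loglik = %.4f\n",
              x$n, x$sigma_u2, x$sigma_e2, x$loglik))
  invisible(x)
}

#' Full-model variance components for the joint effect of a predictor gene
#'
#' ML fit of the four-variance-component model in which the predictor
#' gene's fixed slope is absorbed into a variance component:
#' \deqn{\mathrm{Var}(y) = \sigma_X^2\, xx^\top
#'   + \sigma_{Int}^2\, \mathrm{diag}(x)\Sigma\,\mathrm{diag}(x)
#'   + \sigma_u^2\, \Sigma + \sigma_e^2 I,}
#' with fixed effects \eqn{Z\gamma}. \eqn{\sigma_X^2} carries the overall
#' expression-expression slope, \eqn{\sigma_{Int}^2} the splicing-induced
#' random slope. All kernels are low rank, so likelihood evaluations use
#' Woodbury identities on an (2r+1)-dimensional core; optimization is
#' multi-start quasi-Newton (L-BFGS-B) on log variance ratios.
#' Non-convergence is flagged, not thrown, so genome scans can continue.
#'
#' @inheritParams fit_null
#' @param n_starts number of deterministic starting points (up to 3).
#' @return list with \code{sigma_X2}, \code{sigma_Int2}, \code{sigma_u2},
#'   \code{sigma_e2}, \code{loglik}, \code{converged}.
#' @export
fit_full_variance_components <- function(y, x, Z, kernel, n_starts = 3) {
  y <- as.numeric(y); x <- as.numeric(x)
  n <- length(y)
  U <- kernel$evectors
  lam <- kernel$evalues
  r <- length(lam)
  Gu <- U * rep(sqrt(lam), each = n)      # n x r, Gu Gu^T = Sigma
  Gi <- Gu * x                            # diag(x) Gu
  G <- cbind(Gu, Gi, x)                   # n x (2r+1)
  m <- ncol(G)
  idx <- list(u = seq_len(r), int = r + seq_len(r), X = m)

  Z <- as.matrix(Z)
  p <- ncol(Z)
  GtG <- crossprod(G)
  GtZ <- crossprod(G, Z)
  Gty <- crossprod(G, y)
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  yty <- sum(y^2)

  negll <- function(ldelta) {
    a <- numeric(m)
    a[idx$u] <- exp(ldelta[3L]); a[idx$int] <- exp(ldelta[2L])
    a[idx$X] <- exp(ldelta[1L])
    as_ <- sqrt(a)
    S <- diag(m) + (as_ %o% as_) * GtG    # I + A^1/2 G'G A^1/2
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ldet <- 2 * sum(log(diag(R)))
    # Vbar^-1 quadratic forms via Woodbury
    A1 <- ZtZ - crossprod(as_ * GtZ, backsolve(R, forwardsolve(t(R), as_ * GtZ)))
    b1 <- Zty - crossprod(as_ * GtZ, backsolve(R, forwardsolve(t(R), as_ * Gty)))
    q1 <- yty - sum((as_ * drop(Gty)) *
                      backsolve(R, forwardsolve(t(R), as_ * drop(Gty))))
    gamma <- tryCatch(solve(A1, b1), error = function(e) NULL)
    if (is.null(gamma)) return(1e10)
    rss <- max(q1 - sum(gamma * b1), 1e-300)
    s2 <- rss / n
    0.5 * (n * log(2 * pi * s2) + ldet + n)
  }

  starts <- list(log(c(0.5, 0.5, 0.5)),
                 log(c(0.05, 1, 0.05)),
                 log(c(1, 0.05, 1)))[seq_len(min(n_starts, 3))]
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = rep(-18, 3), upper = rep(8, 3),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(list(sigma_X2 = NA_real_, sigma_Int2 = NA_real_,
                sigma_u2 = NA_real_, sigma_e2 = NA_real_,
                loglik = NA_real_, converged = FALSE))

  ld <- best$par
  # recover sigma_e2 at the optimum
  a <- numeric(m)
  a[idx$u] <- exp(ld[3L]); a[idx$int] <- exp(ld[2L]); a[idx$X] <- exp(ld[1L])
  as_ <- sqrt(a)
  S <- diag(m) + (as_ %o% as_) * GtG
  R <- chol(S)
  A1 <- ZtZ - crossprod(as_ * GtZ, backsolve(R, forwardsolve(t(R), as_ * GtZ)))
  b1 <- Zty - crossprod(as_ * GtZ, backsolve(R, forwardsolve(t(R), as_ * Gty)))
  q1 <- yty - sum((as_ * drop(Gty)) *
                    backsolve(R, forwardsolve(t(R), as_ * drop(Gty))))
  gamma <- solve(A1, b1)
  s2 <- max(q1 - sum(gamma * b1), 0) / n
  # ratios at the lower optimization bound are boundary (zero) estimates
  zero <- ld <= -18 + 1e-6
  d <- exp(ld); d[zero] <- 0
  list(sigma_X2 = d[1L] * s2, sigma_Int2 = d[2L] * s2,
       sigma_u2 = d[3L] * s2, sigma_e2 = s2,
       loglik = -best$value, converged = best$convergence == 0)
}
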