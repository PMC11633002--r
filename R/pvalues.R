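# Tail probabilities of weighted sums of 1-df chi-square variables,
# P(sum_i lambda_i chi^2_1 >= Q): Liu-Tang-Zhang four-cumulant moment
# matching (fast, used genome-wide) and exact numerical inversion of the
# characteristic function (Imhof-type integral, used as the accurate
# reference and as a fallback in the far tail where moment matching is
# known to drift). Also the Cauchy combination used to aggregate the
# joint test's rho grid.

#' Liu moment-matching p-value for a chi-square mixture
#'
#' Approximates \eqn{P(\sum_i \lambda_i \chi^2_1 \ge Q)} by matching the
#' first four cumulants to a (possibly noncentral) scaled chi-square
#' (the Liu-Tang-Zhang variant with the modified kurtosis matching). With
#' a single weight the approximation is exact.
#'
#' @param Q observed statistic (scalar, \eqn{\ge 0}).
#' @param weights nonnegative mixture weights, not all zero.
#' @return p-value in [0, 1].
#' @export
liu_pvalue <- function(Q, weights) {
  if (length(Q) != 1L || is.na(Q) || Q < 0)
    stop_splicecor("Q must be a nonnegative scalar",
                   class = "splicecor_domain_error")
  w <- weights[weights > 0]
  if (!length(w))
    stop_splicecor("all mixture weights are zero",
                   class = "splicecor_domain_error")
  if (Q == 0) return(1)
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  muQ <- c1
  sigmaQ <- sqrt(2 * c2)
  tstar <- (Q - muQ) / sigmaQ
  q_norm <- tstar * sqrt(2 * l + 4 * d) + l + d
  p <- stats::pchisq(q_norm, df = l, ncp = d, lower.tail = FALSE)
  min(max(p, 0), 1)
}

# Ruben's chi-square series: P(sum lambda_i chi^2_1 <= q) expanded as a
# mixture of central chi-square cdfs with common scale beta. With
# beta = 2 l_min l_max / (l_min + l_max), |1 - beta/l_i| <= (R-1)/(R+1)
# (R the eigenvalue spread), so the series converges geometrically.
# Returns the survival probability, or NA if not converged.
ruben_survival <- function(Q, w, tol = 1e-14) {
  m <- length(w)
  beta <- 2 * min(w) * max(w) / (min(w) + max(w))
  qb <- Q / beta
  # chi-square survival terms only become non-negligible once the df
  # reaches the quantile, so the term budget must scale with Q/beta
  max_terms <- min(50000L, max(5000L, ceiling(qb / 2) + 2000L))
  h <- 1 - beta / w
  a <- numeric(max_terms + 1L)
  a[1L] <- exp(0.5 * sum(log(beta / w)))
  gam <- vapply(seq_len(max_terms), function(k) 0.5 * sum(h^k), 0)
  p <- a[1L] * stats::pchisq(qb, df = m, lower.tail = FALSE)
  small_run <- 0L
  for (k in seq_len(max_terms)) {
    j <- seq_len(k)
    a[k + 1L] <- sum(gam[j] * a[k - j + 1L]) / k
    term <- a[k + 1L] * stats::pchisq(qb, df = m + 2 * k, lower.tail = FALSE)
    p <- p + term
    small_run <- if (abs(term) < tol * max(p, 1e-300)) small_run + 1L else 0L
    # never stop while the chi-square mean still trails the quantile:
    # terms are then still on their way up
    if (small_run >= 10L && k > 20L && (m + 2 * k) > qb)
      return(min(max(p, 0), 1))
  }
  NA_real_
}

#' Exact mixture-of-chi-square p-value
#'
#' Computes \eqn{P(\sum_i \lambda_i \chi^2_1 \ge Q)} to numerical
#' accuracy. The primary route is Ruben's expansion of the distribution
#' as an infinite mixture of central chi-squares on a common scale,
#' truncated once terms fall below 1e-14 relative. If the series fails
#' to converge, numerical inversion of the characteristic function
#' (Imhof's integral)
#' \deqn{p = \tfrac12 + \frac{1}{\pi}\int_0^\infty
#'   \frac{\sin\theta(u)}{u\,\rho(u)}\,du}
#' is attempted; if that also fails the Liu approximation is returned
#' with attribute \code{fallback = TRUE}.
#'
#' @inheritParams liu_pvalue
#' @return p-value in [0, 1].
#' @export
davies_pvalue <- function(Q, weights) {
  if (length(Q) != 1L || is.na(Q) || Q < 0)
    stop_splicecor("Q must be a nonnegative scalar",
                   class = "splicecor_domain_error")
  w <- weights[weights > 0]
  if (!length(w))
    stop_splicecor("all mixture weights are zero",
                   class = "splicecor_domain_error")
  if (Q == 0) return(1)
  # weights carrying < 1e-7 of the total scale perturb the tail by less
  # than the integration tolerance; dropping them keeps the series
  # length bounded
  w <- w[w > 1e-7 * sum(w)]
  p <- ruben_survival(Q, w)
  if (!is.na(p)) return(p)
  integrand <- function(u) {
    out <- numeric(length(u))
    pos <- u > 0
    up <- u[pos]
    theta <- 0.5 * colSums(atan(outer(w, up))) - 0.5 * Q * up
    lrho <- 0.25 * colSums(log1p(outer(w^2, up^2)))
    out[pos] <- sin(theta) / (up * exp(lrho))
    out[!pos] <- 0.5 * (sum(w) - Q)      # limit at u = 0
    out
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 2000L, stop.on.error = TRUE)$value,
    error = function(e) NULL)
  if (is.null(val)) {
    p <- liu_pvalue(Q, weights)
    attr(p, "fallback") <- TRUE
    return(p)
  }
  min(max(0.5 + val / pi, 0), 1)
}

# Mixture p-value dispatch: Liu everywhere, exact inversion in the far
# tail where the moment approximation degrades.
mixture_pvalue <- function(Q, weights, method = c("auto", "liu", "davies")) {
  method <- match.arg(method)
  if (method == "liu") return(liu_pvalue(Q, weights))
  if (method == "davies") return(davies_pvalue(Q, weights))
  p <- liu_pvalue(Q, weights)
  if (p < 1e-4) {
    pd <- davies_pvalue(Q, weights)
    if (is.null(attr(pd, "fallback"))) p <- as.numeric(pd)
  }
  p
}

#' Cauchy combination of dependent p-values
#'
#' Aggregates p-values by averaging their Cauchy transforms
#' \eqn{\tan((0.5 - p)\pi)}; the combined p-value is valid under
#' arbitrary dependence among components, which is what makes it usable
#' across the correlated rho grid of the joint test.
#'
#' @param p numeric vector of p-values.
#' @param weights optional nonnegative combination weights (default equal).
#' @return combined p-value in [0, 1].
#' @export
cauchy_combine <- function(p, weights = NULL) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  assert_prob(p)
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  weights <- weights / sum(weights)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  small <- p < 1e-16
  t_ <- numeric(length(p))
  t_[!small] <- tan((0.5 - p[!small]) * pi)
  t_[small] <- 1 / (p[small] * pi)
  stat <- sum(weights * t_)
  if (stat > 1e15) return(1 / (stat * pi))
  min(max(stats::pcauchy(stat, lower.tail = FALSE), 0), 1)
}
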