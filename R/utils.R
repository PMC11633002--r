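# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncate near-zero eigenvalues
#'
#' Eigenvalues below \code{tol * max(ev)} are set to exactly 0 so that all
#' downstream mixture weights agree on which directions are null.
#'
#' @param ev numeric vector of eigenvalues (any order).
#' @param tol relative truncation threshold.
#' @return numeric vector with small entries replaced by 0.
#' @keywords internal
truncate_eigenvalues <- function(ev, tol = 1e-8) {
  if (!length(ev)) return(ev)
  m <- max(ev, 0)
  ev[ev < tol * m] <- 0
  ev
}

stop_splicecor <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "splicecor_error", "error", "condition")))
}

warn_splicecor <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(p, name = "p") {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop_splicecor("%s values outside [0, 1]", name,
                               class = "splicecor_domain_error")
  invisible(p)
}
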