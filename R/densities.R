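# Log densities used by the complete log likelihood.  Written in closed form
# via lgamma so they vectorize over the cohort inside the optimizer.

#' Multinomial log probability mass
#'
#' Full log pmf including the log multinomial coefficient, so that reported
#' likelihood values are comparable across parameter settings (the
#' coefficient is constant in the parameters and does not affect
#' optimization).  The convention 0 log 0 = 0 applies to genes with zero
#' counts.
#'
#' @param counts Vector of non-negative integer counts.
#' @param probs Probability vector of the same length, summing to 1 within
#'   1e-8.
#' @return The log probability mass; `-Inf` (with a warning) when a positive
#'   count falls on a zero-probability gene.
#' @export
multinomial_loglik <- function(counts, probs) {
  if (length(counts) != length(probs))
    stop("counts and probs must have equal length", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("probs must sum to 1 (within 1e-8)", call. = FALSE)
  pos <- counts > 0
  if (any(pos & probs == 0)) {
    warning("positive count on zero-probability gene: log likelihood is -Inf")
    return(-Inf)
  }
  n <- sum(counts)
  lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(counts[pos] * log(probs[pos]))
}

#' Dirichlet log density
#'
#' Standard Dirichlet log pdf at an interior point of the simplex.
#'
#' @param x Simplex vector with all entries strictly positive.
#' @param alpha Concentration parameters, all strictly positive.
#' @return The log density.
#' @export
dirichlet_logpdf <- function(x, alpha) {
  if (length(x) != length(alpha))
    stop("x and alpha must have equal length", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha must be strictly positive", call. = FALSE)
  if (any(x <= 0))
    stop("x lies on the simplex boundary; the density requires an interior ",
         "point (use the interior parameterization)", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-6)
    stop("x must lie on the probability simplex", call. = FALSE)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Log multinomial coefficient per column of a count matrix (constant in the
# model parameters; computed once per fit).
log_multinom_coef <- function(counts) {
  lgamma(colSums(counts) + 1) - colSums(lgamma(counts + 1))
}
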