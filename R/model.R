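# Model state and the complete log likelihood.
#
# Each post-treatment count profile p_n is modeled as
#   p_n | B, r, theta_n  ~  Multinomial(total_n, [B r] theta_n)
# with Dirichlet priors
#   theta_n ~ Dirichlet(v)        (v_d >= 1)
#   r       ~ Dirichlet(kappa * omega B)
# where B is the column-stochastic reference panel, r the shared
# treatment-response profile, theta_n the per-patient mixing weights whose
# (M+1)-th entry is the percent treatment response, omega an M-simplex blend
# of references, and kappa the prior strength on r.

#' Mixture expression profile implied by one patient's weights
#'
#' Computes \eqn{\hat p_n = [B\, r]\,\theta_n}: the convex combination of the
#' M reference profiles and the treatment-response profile with weights
#' `theta_row`.  Because every component is a probability distribution over
#' genes and the weights lie on the simplex, the result is again a
#' distribution over genes.
#'
#' @param panel A [normalize_reference()] reference panel (G x M).
#' @param response Treatment-response profile: G-vector on the simplex.
#' @param theta_row (M+1)-vector of mixing weights on the simplex; the last
#'   entry is the weight of the response profile.
#' @return G-vector of mixture probabilities (sums to 1).
#' @export
mixture_profile <- function(panel, response, theta_row) {
  if (length(theta_row) != ncol(panel) + 1L)
    stop("theta_row must have M + 1 entries", call. = FALSE)
  if (length(response) != nrow(panel))
    stop("response length must match the panel's gene count", call. = FALSE)
  if (any(theta_row < -1e-6) || abs(sum(theta_row) - 1) > 1e-6)
    stop("theta_row is off the probability simplex", call. = FALSE)
  m <- ncol(panel)
  drop(panel %*% theta_row[seq_len(m)]) + response * theta_row[m + 1L]
}

#' Initialize the model state
#'
#' Deterministic/seeded starting point for one optimization restart:
#' all theta entries equal to 1/(M+1); kappa = 10,000; the Dirichlet prior
#' `v` drawn as 1 + Uniform(0,1) for the M reference entries and
#' 5 + Uniform(0,1) for the response entry (the response proportion gets the
#' larger prior because a single profile must absorb it); omega uniform at
#' 1/M; and r started at its prior mean direction, omega B.
#'
#' @param panel Reference panel (G x M).
#' @param counts Companion [discretize_counts()] matrix (G x N), gene ids
#'   identical in content and order.
#' @param seed Integer seed for the `v` draw.
#' @return A `model_state` list: `panel`, `counts`, `theta` (N x (M+1)),
#'   `response`, `hyper` (`v`, `omega`, `kappa`), `loglik_trace`, `seed`.
#' @export
init_state <- function(panel, counts, seed = 1L) {
  check_gene_alignment(panel, counts)
  g <- nrow(panel); m <- ncol(panel); n <- ncol(counts)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  v <- c(1 + stats::runif(m), 5 + stats::runif(1))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  omega <- rep(1 / m, m)
  r <- drop(panel %*% omega)
  # keep r strictly interior even if some gene row of B is (numerically) zero
  r <- pmax(r, 1e-300)
  r <- r / sum(r)
  theta <- matrix(1 / (m + 1L), nrow = n, ncol = m + 1L,
                  dimnames = list(colnames(counts),
                                  c(colnames(panel), "treatment_response")))
  # kappa starts at 10,000, lifted if needed so kappa * omega B >= 1
  # everywhere (the prior on r must have all concentrations >= 1 for the
  # MAP to be well-posed; see the kappa block in fit.R)
  kappa0 <- max(10000, 1 / min(r))
  state <- list(panel = panel, counts = counts, theta = theta, response = r,
                hyper = list(v = v, omega = omega, kappa = kappa0),
                loglik_trace = numeric(0), seed = seed)
  class(state) <- "model_state"
  state
}

#' Complete log likelihood of a model state
#'
#' \deqn{\ln L = \ln P(r \mid \kappa, \omega, B) + \sum_n [\ln P(\theta_n
#' \mid v) + \ln P(p_n \mid B, r, \theta_n)]}
#' The Dirichlet parameter for r is the G-vector \eqn{\kappa\,\omega B}.
#' Multinomial terms include the count-dependent log coefficient.
#'
#' @param state A `model_state`.
#' @return The complete log likelihood (scalar).
#' @export
complete_loglik <- function(state) {
  with(state, {
    alpha_r <- hyper$kappa * drop(panel %*% hyper$omega)
    lp_r <- dirichlet_logpdf(response, alpha_r)
    if (!is.finite(lp_r))
      stop("non-finite likelihood term: Dirichlet prior on the response profile",
           call. = FALSE)
    lp_theta <- sum(apply(theta, 1L, dirichlet_logpdf, alpha = hyper$v))
    if (!is.finite(lp_theta))
      stop("non-finite likelihood term: Dirichlet prior on theta", call. = FALSE)
    phat <- cbind(panel, response) %*% t(theta)        # G x N
    pos <- counts > 0
    if (any(phat[pos] == 0)) return(-Inf)
    lp_counts <- sum(log_multinom_coef(counts)) + sum(counts[pos] * log(phat[pos]))
    if (is.nan(lp_counts))
      stop("non-finite likelihood term: multinomial count likelihood",
           call. = FALSE)
    lp_r + lp_theta + lp_counts
  })
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("Model state: G=%d genes, M=%d references, N=%d post samples\n",
              nrow(x$panel), ncol(x$panel), ncol(x$counts)))
  if (length(x$loglik_trace))
    cat(sprintf("  complete log likelihood: %.4f (%d outer iterations)\n",
                x$loglik_trace[length(x$loglik_trace)], length(x$loglik_trace)))
  invisible(x)
}

# Internal validation of a model state's invariants (used by tests and the
# synthetic generator).
validate_state <- function(state, tol = 1e-8) {
  stopifnot(
    inherits(state$panel, "reference_panel"),
    inherits(state$counts, "count_matrix"),
    nrow(state$theta) == ncol(state$counts),
    ncol(state$theta) == ncol(state$panel) + 1L,
    all(abs(rowSums(state$theta) - 1) < tol),
    all(state$theta >= -tol), all(state$theta <= 1 + tol),
    abs(sum(state$response) - 1) < tol,
    all(state$response > 0),
    all(state$hyper$v >= 1),
    abs(sum(state$hyper$omega) - 1) < tol,
    all(state$hyper$omega >= -tol),
    state$hyper$kappa > 0
  )
  invisible(TRUE)
}
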