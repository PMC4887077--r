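# Standard modelling methods for the fitted "respdecon" object.

#' @export
print.respdecon <- function(x, ...) {
  st <- x$state
  cat("Treatment-response deconvolution (Dirichlet-multinomial mixture)\n")
  cat(sprintf("  %d genes, %d reference profiles, %d post-treatment profiles\n",
              nrow(st$panel), ncol(st$panel), ncol(st$counts)))
  cat(sprintf("  complete log likelihood: %.2f (best of %d restart%s)\n",
              logLik(x), x$control$n_restarts,
              if (x$control$n_restarts > 1) "s" else ""))
  cat(sprintf("  %d outer iterations; %sconverged at rel_tol %.0e\n",
              x$iterations_used, if (isTRUE(x$converged)) "" else "NOT ",
              x$control$rel_tol))
  pr <- extract_treatment_response(x)
  cat(sprintf("  %% treatment response: median %.3f, range [%.3f, %.3f]\n",
              stats::median(pr), min(pr), max(pr)))
  invisible(x)
}

#' @export
summary.respdecon <- function(object, ...) {
  pr <- extract_treatment_response(object)
  dom <- dominant_reference(object)
  out <- list(fit = object,
              pct_response = pr,
              dominant = dom,
              kappa = object$state$hyper$kappa,
              v = object$state$hyper$v,
              omega = object$state$hyper$omega,
              per_restart_logliks = object$per_restart_logliks)
  class(out) <- "summary.respdecon"
  out
}

#' @export
print.summary.respdecon <- function(x, ...) {
  print(x$fit)
  cat("\nPer-patient % treatment response:\n")
  print(round(x$pct_response, 4))
  cat("\nDominant reference per patient:\n")
  print(x$dominant)
  cat(sprintf("\nkappa = %.1f; v range [%.2f, %.2f] (response entry %.2f)\n",
              x$kappa, min(x$v), max(x$v), x$v[length(x$v)]))
  cat("Restart log likelihoods:\n")
  print(round(x$per_restart_logliks, 2))
  invisible(x)
}

#' Mixing weights of a fitted deconvolution
#'
#' @param object A fitted [respdecon()] object.
#' @param ... Unused.
#' @return The N x (M+1) matrix of per-patient mixing weights; the last
#'   column is the percent treatment response.
#' @export
coef.respdecon <- function(object, ...) object$state$theta

#' @export
logLik.respdecon <- function(object, ...) {
  tr <- object$state$loglik_trace
  structure(tr[length(tr)], class = "logLik",
            df = length(object$state$response) - 1 +
              prod(dim(object$state$theta) - c(0, 1)) +
              length(object$state$hyper$v) +
              length(object$state$hyper$omega))
}

#' Fitted mixture profiles
#'
#' @param object A fitted [respdecon()] object.
#' @param ... Unused.
#' @return G x N matrix of fitted per-gene probabilities `[B r] theta_n`
#'   (each column sums to 1).
#' @export
fitted.respdecon <- function(object, ...) {
  st <- object$state
  out <- cbind(st$panel, st$response) %*% t(st$theta)
  dimnames(out) <- list(rownames(st$panel), colnames(st$counts))
  out
}

#' Predict expected counts or mixture profiles
#'
#' @param object A fitted [respdecon()] object.
#' @param type `"counts"` (expected counts, fitted probabilities times each
#'   sample's total) or `"probs"` (the mixture profiles themselves).
#' @param ... Unused.
#' @return G x N matrix.
#' @export
predict.respdecon <- function(object, type = c("counts", "probs"), ...) {
  type <- match.arg(type)
  probs <- fitted(object)
  if (type == "probs") return(probs)
  sweep(probs, 2L, attr(object$state$counts, "totals"), "*")
}

#' Pearson residuals of the fitted deconvolution
#'
#' Observed minus expected counts, scaled by the multinomial standard
#' deviation `sqrt(T p (1 - p))`.
#'
#' @param object A fitted [respdecon()] object.
#' @param ... Unused.
#' @return G x N matrix of Pearson residuals.
#' @export
residuals.respdecon <- function(object, ...) {
  st <- object$state
  probs <- fitted(object)
  tot <- attr(st$counts, "totals")
  expected <- sweep(probs, 2L, tot, "*")
  vr <- sweep(probs * (1 - probs), 2L, tot, "*")
  (unclass(st$counts) - expected) / sqrt(pmax(vr, .Machine$double.eps))
}

#' Simulate count matrices from a fitted deconvolution
#'
#' Parametric-bootstrap draws: each simulated sample is a multinomial draw
#' of the observed total from the patient's fitted mixture profile.
#'
#' @param object A fitted [respdecon()] object.
#' @param nsim Number of simulated count matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` `count_matrix` objects.
#' @export
simulate.respdecon <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  probs <- fitted(object)
  tot <- attr(object$state$counts, "totals")
  replicate(nsim, {
    sim <- vapply(seq_len(ncol(probs)),
                  function(j) stats::rmultinom(1L, tot[j], probs[, j])[, 1L],
                  numeric(nrow(probs)))
    dimnames(sim) <- dimnames(probs)
    as_count_matrix(sim)
  }, simplify = FALSE)
}

#' Diagnostic plots for a fitted deconvolution
#'
#' Two base-graphics panels: the complete log-likelihood trace across outer
#' iterations, and the sorted per-patient percent treatment response.
#'
#' @param x A fitted [respdecon()] object.
#' @param which Integer subset of `1:2` selecting panels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.respdecon <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    tr <- x$state$loglik_trace
    graphics::plot(seq_along(tr) - 1L, tr, type = "b", pch = 16,
                   xlab = "outer iteration", ylab = "complete log likelihood",
                   main = "Optimization trace", ...)
  }
  if (2 %in% which) {
    pr <- sort(extract_treatment_response(x))
    graphics::plot(seq_along(pr), pr, pch = 16, col = "darkgreen",
                   xlab = "patient (sorted)", ylab = "% treatment response",
                   ylim = c(0, max(pr) * 1.1),
                   main = "Per-patient % treatment response", ...)
  }
  invisible(x)
}
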