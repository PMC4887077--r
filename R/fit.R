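# MAP estimation by block conjugate-gradient ascent with random restarts.
#
# Each outer iteration cycles the parameter blocks in the fixed order
# theta -> response -> v -> omega -> kappa.  Every block is optimized through
# a smooth interior reparameterization (softmax for simplex blocks, 1+exp for
# v and kappa), so Dirichlet boundary evaluations never occur and a monotone
# line search makes the complete log likelihood non-decreasing by
# construction.

BLOCK_ORDER <- c("theta", "response", "v", "omega", "kappa")

#' Control parameters for model fitting
#'
#' @param max_outer Maximum outer iterations (full block cycles). Default 35.
#' @param rel_tol Convergence threshold on the relative change of the
#'   complete log likelihood between outer iterations. Default 1e-7.
#' @param n_restarts Number of random restarts; the restart with the highest
#'   final complete log likelihood wins. Default 10.
#' @param cg_max_steps Maximum conjugate-gradient steps per block per outer
#'   iteration. Default 100.
#' @param seed Integer seed; restart k uses `seed + k - 1`.
#' @param update Character vector of blocks to update; blocks omitted here
#'   stay frozen at their initialization (useful for oracle comparisons and
#'   what-if analyses).
#' @return A list of class `respdecon_control`.
#' @export
respdecon_control <- function(max_outer = 35L, rel_tol = 1e-7,
                              n_restarts = 10L, cg_max_steps = 100L,
                              seed = 1L, update = BLOCK_ORDER) {
  stopifnot(max_outer >= 1L, rel_tol > 0, n_restarts >= 1L,
            cg_max_steps >= 1L, all(update %in% BLOCK_ORDER))
  structure(list(max_outer = as.integer(max_outer), rel_tol = rel_tol,
                 n_restarts = as.integer(n_restarts),
                 cg_max_steps = as.integer(cg_max_steps),
                 seed = as.integer(seed), update = update),
            class = "respdecon_control")
}

#' Optimize one parameter block in place
#'
#' Runs conjugate-gradient ascent on the named block with all other blocks
#' held fixed.  The block-local objective differs from the complete log
#' likelihood only by terms constant in the block, so a monotone line search
#' guarantees the complete log likelihood cannot decrease.
#'
#' @param state A `model_state` (see [init_state()]).
#' @param block One of `"theta"`, `"response"`, `"v"`, `"omega"`, `"kappa"`.
#' @param cg_max_steps Maximum CG steps.
#' @return The updated `model_state`.
#' @export
optimize_block <- function(state, block = BLOCK_ORDER, cg_max_steps = 100L) {
  block <- match.arg(block)
  obj <- block_objective(state, block)
  res <- cg_maximize(obj$par0, obj$val, obj$grad, max_steps = cg_max_steps)
  # the unconstrained start may not represent the current state exactly
  # (e.g. kappa sitting below a floor that rose with omega); apply the
  # update only if it does not lose ground against the true current value,
  # so the complete log likelihood never decreases
  cur <- if (is.null(obj$cur)) obj$val(obj$par0) else obj$cur
  if (is.finite(cur) && res$value < cur) return(state)
  obj$put(state, res$par)
}

# Builds the block-local objective: starting unconstrained parameter, value
# and gradient closures, and a writer mapping the optimum back into the
# state.  All fixed quantities are captured once.
block_objective <- function(state, block) {
  B <- state$panel
  P <- state$counts
  theta <- state$theta
  r <- state$response
  v <- state$hyper$v
  omega <- state$hyper$omega
  kappa <- state$hyper$kappa
  m <- ncol(B)

  switch(block,
    theta = {
      A <- cbind(B, r)
      n_rows <- nrow(theta)
      # log-softmax kept explicit: the Dirichlet term (v-1) * log(theta)
      # stays finite even when a weight underflows to double-precision zero,
      # and (v-1)/theta * theta cancels analytically in the gradient.
      val_m <- function(z) {
        lth <- z - apply(z, 1L, logsumexp)
        th <- exp(lth)
        phat <- A %*% t(th)
        s <- sum(P * log(phat))
        if (!is.finite(s)) return(-Inf)
        s + sum(lth %*% (v - 1))
      }
      grad_m <- function(z) {
        th <- row_softmax(z)
        phat <- A %*% t(th)
        gd <- t(crossprod(A, P / phat))
        th * gd + matrix(v - 1, nrow(th), ncol(th), byrow = TRUE) -
          th * (rowSums(th * gd) + sum(v - 1))
      }
      list(par0 = as.vector(log(theta)),
           val = function(z) val_m(matrix(z, n_rows)),
           grad = function(z) as.vector(grad_m(matrix(z, n_rows))),
           put = function(st, par) {
             st$theta[] <- pmax(row_softmax(matrix(par, n_rows)),
                                .Machine$double.xmin)
             st
           })
    },
    response = {
      Cfix <- B %*% t(theta[, seq_len(m), drop = FALSE])   # G x N
      w <- theta[, m + 1L]
      ar <- kappa * drop(B %*% omega)
      val <- function(z) {
        lr <- z - logsumexp(z)
        rr <- exp(lr)
        phat <- Cfix + outer(rr, w)
        s <- sum(P * log(phat))
        if (!is.finite(s)) return(-Inf)
        s + sum((ar - 1) * lr)
      }
      grad <- function(z) {
        rr <- softmax(z)
        phat <- Cfix + outer(rr, w)
        gd <- drop((P / phat) %*% w)
        rr * gd + (ar - 1) - rr * (sum(rr * gd) + sum(ar - 1))
      }
      list(par0 = log(r), val = val, grad = grad,
           put = function(st, par) {
             st$response <- pmax(softmax(par), .Machine$double.xmin)
             st
           })
    },
    v = {
      n <- nrow(theta)
      S <- colSums(log(theta))
      val <- function(u) {
        vv <- 1 + exp(pmin(u, 30))
        n * lgamma(sum(vv)) - n * sum(lgamma(vv)) + sum((vv - 1) * S)
      }
      grad <- function(u) {
        vv <- 1 + exp(pmin(u, 30))
        gv <- n * digamma(sum(vv)) - n * digamma(vv) + S
        gv * (vv - 1) * (u < 30)
      }
      list(par0 = log(pmax(v - 1, 1e-12)), val = val, grad = grad,
           put = function(st, par) {
             st$hyper$v <- 1 + exp(pmin(par, 30))
             st
           })
    },
    omega = {
      lr <- log(r)
      val <- function(z) {
        om <- softmax(z)
        al <- kappa * drop(B %*% om)
        -sum(lgamma(al)) + sum((al - 1) * lr)
      }
      grad <- function(z) {
        om <- softmax(z)
        al <- kappa * drop(B %*% om)
        gom <- kappa * drop(crossprod(B, lr - digamma(al)))
        om * (gom - sum(om * gom))
      }
      list(par0 = log(omega), val = val, grad = grad,
           put = function(st, par) { st$hyper$omega <- softmax(par); st })
    },
    kappa = {
      al0 <- drop(B %*% omega)
      lr <- log(r)
      # kappa is floored so every entry of the Dirichlet concentration
      # kappa * omega B stays >= 1: below that the prior log-density
      # diverges at the simplex boundary and the MAP for r is ill-posed
      # (r collapses to a spike while the response weights go to zero).
      k_min <- max(1, 1 / min(al0))
      val <- function(t) {
        k <- k_min + exp(pmin(t, 30))
        lgamma(k) - sum(lgamma(k * al0)) + sum((k * al0 - 1) * lr)
      }
      grad <- function(t) {
        k <- k_min + exp(pmin(t, 30))
        gk <- digamma(k) - sum(al0 * digamma(k * al0)) + sum(al0 * lr)
        gk * (k - k_min) * (t < 30)
      }
      cur_val <- lgamma(kappa) - sum(lgamma(kappa * al0)) +
        sum((kappa * al0 - 1) * lr)
      list(par0 = log(max(kappa - k_min, 1e-8)), val = val, grad = grad,
           cur = cur_val,
           put = function(st, par) {
             st$hyper$kappa <- k_min + exp(min(par, 30))
             st
           })
    }
  )
}

#' Deconvolve post-treatment profiles into references plus a shared
#' treatment-response profile
#'
#' Fits the Dirichlet-multinomial mixture model by MAP estimation: each
#' post-treatment count profile is explained as a convex combination of the
#' M pre-treatment reference profiles and one hidden treatment-response
#' profile shared by the whole cohort.  The weight each patient places on
#' the shared profile is the percent treatment response.
#'
#' For each random restart the parameter blocks are cycled in the fixed
#' order theta, response, v, omega, kappa until the relative change in
#' complete log likelihood drops below `control$rel_tol` or
#' `control$max_outer` iterations are reached; the restart with the highest
#' final complete log likelihood is kept.
#'
#' @param panel Reference panel from [normalize_reference()] (G x M).
#' @param counts Count matrix from [discretize_counts()] (G x N), gene ids
#'   identical in content and order to `panel`.
#' @param control A [respdecon_control()] list.
#' @return An object of class `respdecon` with components `state` (the best
#'   `model_state`, including `loglik_trace`), `per_restart_logliks`,
#'   `converged`, `iterations_used`, `control` and `call`.
#' @seealso [extract_treatment_response()], [compute_delta()],
#'   [sensitivity_test()], [clinical_correlations()]
#' @examples
#' sim <- simulate_cohort(cohort_config(G = 120, M = 3, N = 4,
#'                                      total_counts = 2e4, seed = 7))
#' fit <- respdecon(sim$panel, sim$counts,
#'                  control = respdecon_control(n_restarts = 2, max_outer = 8,
#'                                              seed = 7))
#' fit
#' extract_treatment_response(fit)
#' @export
respdecon <- function(panel, counts, control = respdecon_control()) {
  if (!inherits(panel, "reference_panel"))
    panel <- normalize_reference(panel)
  if (!inherits(counts, "count_matrix"))
    counts <- as_count_matrix(counts)
  check_gene_alignment(panel, counts)
  zero_rows <- rowSums(panel) == 0
  if (any(zero_rows))
    stop("gene(s) with zero expression in every reference profile: ",
         paste(utils::head(rownames(panel)[zero_rows], 5), collapse = ", "),
         "; filter them before fitting", call. = FALSE)

  best <- NULL
  per_restart <- rep(NA_real_, control$n_restarts)
  for (k in seq_len(control$n_restarts)) {
    st <- tryCatch(
      run_restart(panel, counts, control, seed = control$seed + k - 1L),
      error = function(e) {
        warning(sprintf("restart %d failed: %s", k, conditionMessage(e)))
        NULL
      })
    if (is.null(st)) next
    ll <- st$loglik_trace[length(st$loglik_trace)]
    per_restart[k] <- ll
    if (is.null(best) || ll > best$ll) best <- list(state = st, ll = ll)
  }
  if (is.null(best) || !any(is.finite(per_restart)))
    stop("model fit failed: no restart produced a finite likelihood",
         call. = FALSE)
  trace <- best$state$loglik_trace
  out <- list(state = best$state,
              per_restart_logliks = per_restart,
              converged = attr(best$state, "converged"),
              iterations_used = length(trace) - 1L,
              control = control,
              call = match.call())
  class(out) <- "respdecon"
  out
}

run_restart <- function(panel, counts, control, seed) {
  state <- init_state(panel, counts, seed = seed)
  ll <- complete_loglik(state)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(control$max_outer)) {
    for (block in control$update)
      state <- optimize_block(state, block, cg_max_steps = control$cg_max_steps)
    ll_new <- complete_loglik(state)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= control$rel_tol * abs(ll)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  state$loglik_trace <- trace
  attr(state, "converged") <- converged
  state
}

#' Per-patient percent treatment response
#'
#' Extracts the weight each post-treatment profile places on the shared
#' treatment-response profile: the (M+1)-th entry of each patient's mixing
#' weights.
#'
#' @param fit A fitted [respdecon()] object.
#' @return Named numeric vector in `[0, 1]`, keyed by post-treatment sample
#'   id.
#' @export
extract_treatment_response <- function(fit) {
  stopifnot(inherits(fit, "respdecon"))
  th <- fit$state$theta
  stats::setNames(th[, ncol(th)], rownames(th))
}

#' Dominant reference profile per patient
#'
#' For each post-treatment profile, the index of the pre-treatment reference
#' receiving the highest mixing weight (the response column is excluded).
#' Ties break to the lowest index.
#'
#' @param fit A fitted [respdecon()] object.
#' @return Named integer vector of reference indices, keyed by
#'   post-treatment sample id; reference sample ids attached as the
#'   `"reference_id"` attribute.
#' @export
dominant_reference <- function(fit) {
  stopifnot(inherits(fit, "respdecon"))
  th <- fit$state$theta
  m <- ncol(th) - 1L
  idx <- max.col(th[, seq_len(m), drop = FALSE], ties.method = "first")
  structure(stats::setNames(idx, rownames(th)),
            reference_id = colnames(fit$state$panel)[idx])
}
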