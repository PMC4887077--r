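# Generic Polak-Ribiere conjugate-gradient ascent on an unconstrained
# parameter vector, with backtracking (Armijo) line search and automatic
# restart to steepest ascent when the conjugate direction stops being an
# ascent direction.  Used for every parameter block; constraints are handled
# upstream by smooth reparameterization (softmax / log), so `par` is always
# unconstrained here.

cg_maximize <- function(par, val, grad,
                        max_steps = 100L,
                        rel_tol = 1e-10,
                        max_halvings = 50L) {
  f <- val(par)
  if (!is.finite(f)) stop("non-finite objective at the starting point", call. = FALSE)
  g <- grad(par)
  d <- g
  steps <- 0L
  for (step in seq_len(max_steps)) {
    gd <- sum(d * g)
    if (!is.finite(gd) || gd <= 0) {          # restart: steepest ascent
      d <- g
      gd <- sum(g * g)
    }
    if (gd <= 0) break                         # stationary point
    # bounded initial step: at most one unit of movement per coordinate
    t0 <- 1 / max(1, max(abs(d)))
    ls <- line_search_ascent(par, d, f, gd, val, t0, max_halvings)
    if (is.null(ls) && !identical(d, g)) {     # retry from steepest ascent
      d <- g
      gd <- sum(g * g)
      if (gd <= 0) break
      t0 <- 1 / max(1, max(abs(d)))
      ls <- line_search_ascent(par, d, f, gd, val, t0, max_halvings)
    }
    if (is.null(ls)) break                     # no improving step found
    par_new <- par + ls$t * d
    f_new <- ls$f
    g_new <- grad(par_new)
    beta <- sum(g_new * (g_new - g)) / sum(g * g)
    if (!is.finite(beta) || beta < 0) beta <- 0
    d <- g_new + beta * d
    converged <- abs(f_new - f) <= rel_tol * (abs(f) + 1)
    par <- par_new
    f <- f_new
    g <- g_new
    steps <- step
    if (converged) break
  }
  list(par = par, value = f, steps = steps)
}

# Backtracking line search with one-sided expansion.  Returns NULL when no
# step satisfying the Armijo condition is found within `max_halvings`.
line_search_ascent <- function(par, d, f, gd, val, t0, max_halvings) {
  armijo <- function(t, ft) is.finite(ft) && ft >= f + 1e-4 * t * gd
  t <- t0
  ft <- val(par + t * d)
  if (armijo(t, ft)) {
    # greedy expansion while the objective keeps increasing
    for (i in seq_len(20L)) {
      t2 <- 2 * t
      f2 <- val(par + t2 * d)
      if (is.finite(f2) && f2 > ft) { t <- t2; ft <- f2 } else break
    }
    return(list(t = t, f = ft))
  }
  for (i in seq_len(max_halvings)) {
    t <- t / 2
    ft <- val(par + t * d)
    if (armijo(t, ft)) return(list(t = t, f = ft))
  }
  NULL
}

logsumexp <- function(z) {
  m <- max(z)
  m + log(sum(exp(z - m)))
}

# Row-wise and vector softmax (interior of the simplex by construction).
softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
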