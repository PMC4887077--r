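# Shared fixtures, built in code and memoised for the session so expensive
# fits run once across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# small cohort + fit used by many unit tests
tiny_cohort <- function() memo("tiny_cohort", {
  simulate_cohort(cohort_config(G = 120, M = 3, N = 4, total_counts = 2e4,
                                n_de_genes = 8, seed = 42))
})

tiny_fit <- function() memo("tiny_fit", {
  sim <- tiny_cohort()
  respdecon(sim$panel, sim$counts,
            respdecon_control(n_restarts = 2, max_outer = 10, seed = 42))
})

# the standard validation cohort: 1000 genes, 10 references, 12 post
# samples of 1e5 counts, 50 planted DE genes, response weights on
# [0.05, 0.5]; fitted with the default control
recovery_cohort <- function() memo("recovery_cohort", {
  simulate_cohort(cohort_config(seed = 1))
})

recovery_fit <- function() memo("recovery_fit", {
  sim <- recovery_cohort()
  respdecon(sim$panel, sim$counts, respdecon_control(seed = 1))
})

# random small model state (valid, non-degenerate) for likelihood tests
random_state <- function(G = 4, M = 2, N = 3, total = 500, seed = 7) {
  set.seed(seed)
  panel <- normalize_reference(matrix(stats::runif(G * M, 0.2, 2), G, M))
  counts <- discretize_counts(matrix(stats::runif(G * N, 0.2, 2), G, N),
                              target_total = total)
  st <- init_state(panel, counts, seed = seed)
  # move off the symmetric start
  st$theta[] <- t(apply(matrix(stats::rgamma(N * (M + 1), 2), N), 1L,
                        function(x) x / sum(x)))
  st$response <- local({ x <- stats::rgamma(G, 2); x / sum(x) })
  st
}
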