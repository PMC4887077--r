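test_that("optimize_block never decreases the complete log likelihood", {
  st <- random_state(G = 6, M = 2, N = 3, total = 800, seed = 19)
  for (block in c("theta", "response", "v", "omega", "kappa")) {
    before <- complete_loglik(st)
    st <- optimize_block(st, block)
    after <- complete_loglik(st)
    expect_gte(after, before - 1e-9 * abs(before))
  }
  validate_ok <- respdecon:::validate_state(st)
  expect_true(validate_ok)
})

test_that("a block at its optimum is left essentially unchanged", {
  st <- random_state(G = 5, M = 2, N = 2, total = 600, seed = 23)
  st <- optimize_block(st, "theta", cg_max_steps = 400)
  st2 <- optimize_block(st, "theta", cg_max_steps = 400)
  expect_equal(st2$theta, st$theta, tolerance = 1e-3)
  expect_lt(max(abs(st2$theta - st$theta)), 1e-3)
})

test_that("theta-block optimum matches an exhaustive grid search (G=3, M=1, N=1)", {
  set.seed(4)
  panel <- normalize_reference(matrix(c(0.5, 0.3, 0.2), 3, 1))
  truth_p <- c(0.25, 0.3, 0.45)
  counts <- as_count_matrix(matrix(stats::rmultinom(1, 2000, truth_p), 3, 1))
  rownames(counts) <- rownames(panel)
  st <- init_state(panel, counts, seed = 4)
  st$response <- c(0.1, 0.3, 0.6)   # fixed, away from the reference

  st_opt <- optimize_block(st, "theta", cg_max_steps = 500)

  # oracle: evaluate the exact objective on a 1e-3 grid of theta = (t, 1-t)
  grid <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  obj <- vapply(grid, function(t) {
    phat <- mixture_profile(panel, st$response, c(t, 1 - t))
    multinomial_loglik(counts[, 1], phat) +
      dirichlet_logpdf(c(t, 1 - t), st$hyper$v)
  }, numeric(1))
  t_star <- grid[which.max(obj)]
  expect_lt(max(abs(st_opt$theta[1, ] - c(t_star, 1 - t_star))), 5e-3)
})

test_that("full fit with frozen hyperparameters matches the same grid oracle", {
  set.seed(6)
  panel <- normalize_reference(matrix(c(0.45, 0.35, 0.2), 3, 1))
  truth_p <- c(0.2, 0.25, 0.55)
  counts <- as_count_matrix(matrix(stats::rmultinom(1, 3000, truth_p), 3, 1))
  rownames(counts) <- rownames(panel)
  fit <- respdecon(panel, counts,
                   respdecon_control(n_restarts = 1, max_outer = 30,
                                     seed = 6, update = c("theta", "response")))
  st <- fit$state
  grid <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  obj <- vapply(grid, function(t) {
    phat <- mixture_profile(panel, st$response, c(t, 1 - t))
    multinomial_loglik(counts[, 1], phat) +
      dirichlet_logpdf(c(t, 1 - t), st$hyper$v)
  }, numeric(1))
  t_star <- grid[which.max(obj)]
  expect_lt(max(abs(st$theta[1, ] - c(t_star, 1 - t_star))), 5e-3)
})

test_that("fit trace ascends and simplex constraints hold", {
  fit <- tiny_fit()
  tr <- fit$state$loglik_trace
  expect_true(all(diff(tr) >= -1e-9 * abs(tr[-length(tr)])))
  expect_true(all(abs(rowSums(fit$state$theta) - 1) < 1e-8))
  expect_equal(sum(fit$state$response), 1, tolerance = 1e-8)
  expect_true(all(fit$state$response > 0))
  expect_equal(max(fit$per_restart_logliks, na.rm = TRUE),
               as.numeric(logLik(fit)))
})

test_that("identical seeds give bit-identical fits", {
  sim <- tiny_cohort()
  ctl <- respdecon_control(n_restarts = 2, max_outer = 4, seed = 31)
  f1 <- respdecon(sim$panel, sim$counts, ctl)
  f2 <- respdecon(sim$panel, sim$counts, ctl)
  expect_identical(f1$per_restart_logliks, f2$per_restart_logliks)
  expect_identical(f1$state$theta, f2$state$theta)
  expect_identical(f1$state$response, f2$state$response)
})

test_that("percent treatment response and dominant reference extract correctly", {
  fake <- structure(list(state = list(
    theta = matrix(c(0.7, 0.2, 0.1,
                     0.45, 0.45, 0.10), 2, 3, byrow = TRUE,
                   dimnames = list(c("p1", "p2"), NULL)),
    panel = matrix(0, 1, 2, dimnames = list("g", c("refA", "refB"))))),
    class = "respdecon")
  expect_equal(extract_treatment_response(fake), c(p1 = 0.1, p2 = 0.1))
  dom <- dominant_reference(fake)
  expect_equal(as.vector(dom), c(1, 1))   # tie in row 2 breaks low
  expect_equal(attr(dom, "reference_id"), c("refA", "refA"))

  fit <- tiny_fit()
  pr <- extract_treatment_response(fit)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_named(pr, colnames(tiny_cohort()$counts))
})

test_that("model methods are mutually consistent", {
  fit <- tiny_fit()
  probs <- fitted(fit)
  expect_equal(colSums(probs), rep(1, ncol(probs)), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(predict(fit, type = "probs"), probs)
  exp_counts <- predict(fit, type = "counts")
  expect_equal(colSums(exp_counts),
               as.vector(attr(fit$state$counts, "totals")),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(dim(residuals(fit)), dim(probs))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(colSums(sims[[1]]) == attr(fit$state$counts, "totals")))
  expect_equal(coef(fit), fit$state$theta)
})
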