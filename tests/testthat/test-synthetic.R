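test_that("generated objects satisfy their type invariants", {
  sim <- tiny_cohort()
  expect_s3_class(sim$panel, "reference_panel")
  expect_equal(colSums(sim$panel), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(sim$panel >= 0))
  expect_true(all(colSums(sim$counts) == 2e4))
  expect_true(all(sim$counts == floor(sim$counts)))
  th <- sim$truth$true_theta
  expect_equal(rowSums(th), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(th >= 0 & th <= 1))
  expect_equal(sum(sim$truth$true_response), 1, tolerance = 1e-8)
  expect_true(all(sim$truth$planted_ids %in% rownames(sim$panel)))
  w <- th[, 4]
  expect_true(all(w >= 0.05 & w <= 0.5))
})

test_that("the generator is seed-deterministic", {
  cfg <- cohort_config(G = 60, M = 2, N = 3, total_counts = 5000,
                       n_de_genes = 5, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(unclass(s1$panel), unclass(s2$panel))
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$clinical, s2$clinical)
  s3 <- simulate_cohort(cohort_config(G = 60, M = 2, N = 3,
                                      total_counts = 5000, n_de_genes = 5,
                                      seed = 78))
  expect_false(identical(unclass(s1$counts), unclass(s3$counts)))
})

test_that("higher reference concentration gives more similar references", {
  mean_pairwise_cor <- function(conc, seed) {
    p <- gen_reference_panel(cohort_config(G = 80, M = 4, N = 2,
                                           n_de_genes = 0,
                                           ref_concentration = conc,
                                           seed = seed))
    cm <- stats::cor(unclass(p))
    mean(cm[upper.tri(cm)])
  }
  tight <- vapply(1:20, function(s) mean_pairwise_cor(1e4, s), numeric(1))
  loose <- vapply(1:20, function(s) mean_pairwise_cor(10, s), numeric(1))
  expect_gt(mean(tight), mean(loose))
})

test_that("planted response profile is self-consistent with compute_delta", {
  cfg <- cohort_config(G = 200, M = 3, N = 2, n_de_genes = 6, seed = 5)
  panel <- gen_reference_panel(cfg)
  omega <- rep(1 / 3, 3)
  resp <- gen_response_profile(panel, cfg, omega = omega)

  d <- compute_delta(resp$response, list(omega = omega), panel)
  expect_equal(as.numeric(unclass(d)), as.numeric(resp$achieved_log2fc),
               tolerance = 1e-10)

  # with few planted genes the renormalization shift is small
  onegene <- cohort_config(G = 200, M = 3, N = 2, n_de_genes = 1,
                           effect_range = c(2, 2), seed = 6)
  r1 <- gen_response_profile(gen_reference_panel(onegene), onegene,
                             omega = omega)
  expect_lt(abs(abs(r1$planted_effects) - 2), 1e-12)
  expect_lt(abs(abs(r1$achieved_log2fc[r1$planted_ids]) - 2), 0.1)

  # no planted genes: response equals the blend, deltas all zero
  none <- cohort_config(G = 50, M = 3, N = 2, n_de_genes = 0, seed = 7)
  r0 <- gen_response_profile(gen_reference_panel(none), none, omega = omega)
  expect_equal(max(abs(r0$achieved_log2fc)), 0, tolerance = 1e-12)
})

test_that("multinomial sampling concentrates on the mixture profile", {
  cfg <- cohort_config(G = 50, M = 2, N = 1, total_counts = 1e6,
                       n_de_genes = 4, seed = 9)
  panel <- gen_reference_panel(cfg)
  resp <- gen_response_profile(panel, cfg)
  theta <- matrix(c(0.3, 0.4, 0.3), 1)
  counts <- gen_post_counts(panel, resp$response, theta, cfg)
  expect_equal(sum(counts), 1e6)
  p <- mixture_profile(panel, resp$response, theta[1, ])
  expect_lt(sum(abs(counts[, 1] / 1e6 - p)), 0.01)
})

test_that("clinical outcomes track the planted response weights", {
  # noise-free: exact monotone relation for the active joint count
  for (s in c(3, 19, 54)) {
    cfg <- cohort_config(G = 10, M = 3, N = 12, n_de_genes = 0,
                         clinical_noise = 0, seed = s)
    tt <- respdecon:::gen_true_theta(cfg)
    clin <- gen_clinical(list(true_theta = tt$theta), cfg)
    red <- pct_reduction(clin$active_0, clin$active_6)
    expect_equal(stats::cor(tt$theta[, 4], red, method = "spearman"), 1)
    counts_cols <- clin[c("active_0", "active_6", "lrm_0", "lrm_6",
                          "esr_0", "esr_6")]
    expect_true(all(counts_cols >= 0 & counts_cols == floor(as.matrix(counts_cols))))
  }

  # noisy: mean correlation inside the pre-computed calibration band
  rhos <- vapply(1:50, function(s) {
    cfg <- cohort_config(G = 10, M = 3, N = 12, n_de_genes = 0,
                         clinical_noise = 0.2, seed = s)
    tt <- respdecon:::gen_true_theta(cfg)
    clin <- gen_clinical(list(true_theta = tt$theta), cfg)
    stats::cor(tt$theta[, 4], pct_reduction(clin$active_0, clin$active_6),
               method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.78)
  expect_lt(mean(rhos), 0.89)
})
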