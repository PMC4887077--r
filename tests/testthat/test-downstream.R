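test_that("percent reduction reproduces the worked examples", {
  expect_equal(pct_reduction(30, 15), 50)
  expect_equal(pct_reduction(2, 1), 50)
  expect_equal(pct_reduction(10, 12), -20)
  expect_true(is.na(pct_reduction(0, 0)))
  expect_error(pct_reduction(-1, 0), "negative")
})

test_that("outcome correlations match direct-formula oracles", {
  x <- 1:5; y <- c(2, 4, 5, 7, 11)
  expect_equal(correlate_outcome(x, y, "spearman")$rho, 1)
  expect_equal(correlate_outcome(x, -x, "pearson")$rho, -1)

  set.seed(17)
  a <- stats::rnorm(33); b <- stats::rnorm(33)
  sp <- correlate_outcome(a, b, "spearman")
  pe <- correlate_outcome(a, b, "pearson")
  # independent oracles: product-moment formula on ranks / raw values
  pm <- function(u, v) sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(sp$rho, pm(rank(a), rank(b)), tolerance = 1e-10)
  expect_equal(pe$rho, pm(a, b), tolerance = 1e-10)
  expect_equal(sp$n, 33)

  # symmetry
  expect_equal(correlate_outcome(b, a, "spearman")$rho, sp$rho)
  expect_equal(correlate_outcome(b, a, "pearson")$rho, pe$rho)

  # listwise exclusion of undefined pairs
  a[5] <- NA
  expect_equal(correlate_outcome(a, b, "pearson")$n, 32)

  expect_error(correlate_outcome(rep(1, 5), 1:5), "constant")
  expect_error(correlate_outcome(1:2, 1:2), "at least 3")
})

test_that("bonferroni correction reproduces the worked examples and bounds", {
  expect_equal(bonferroni(0.010, 4), 0.040)
  expect_equal(bonferroni(0.008, 4), 0.032)
  expect_equal(bonferroni(0.5, 4), 1.0)
  # monotone in both arguments, never above 1
  p <- seq(0, 1, 0.05)
  expect_true(all(diff(bonferroni(p, 3)) >= 0))
  expect_true(all(bonferroni(p, 7) >= bonferroni(p, 3)))
  expect_true(all(bonferroni(p, 50) <= 1))
  expect_error(bonferroni(1.2, 4), "0, 1")
})

test_that("clinical correlation table ties responses to generated outcomes", {
  sim <- tiny_cohort()
  # noise-free clinical outcomes: active-joint reduction is an exact
  # monotone transform of the true response weight
  cfg0 <- cohort_config(G = 120, M = 3, N = 4, total_counts = 2e4,
                        n_de_genes = 8, clinical_noise = 0, seed = 42)
  clin0 <- gen_clinical(sim$truth, cfg0)
  w <- sim$truth$true_theta[, 4]
  names(w) <- sim$clinical$patient_id
  tab <- clinical_correlations(w, clin0)
  expect_equal(tab$spearman_rho[tab$indicator == "active"], 1)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$spearman_p_bonf <= 1 & tab$pearson_p_bonf <= 1))
})

test_that("sensitivity summaries follow the SE-of-the-mean convention", {
  est <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(stats::sd(est) / 2, 0.06454972, tolerance = 1e-7)
  # identical estimates: exactly zero
  expect_equal(stats::sd(rep(0.3, 4)) / 2, 0)
})

test_that("sensitivity test partitions genes and reports per-patient SEs", {
  sim <- tiny_cohort()
  ctl <- respdecon_control(n_restarts = 1, max_outer = 8, seed = 42)
  res <- sensitivity_test(sim$panel, sim$counts, ctl, n_subsets = 4)
  expect_equal(dim(res$estimates), c(4, 4))
  expect_true(all(res$se >= 0))
  expect_gte(res$max_se, res$average_se)
  expect_length(res$failed, 0)
  # SE invariant to subset label order
  se2 <- apply(res$estimates[, 4:1], 1, function(x) stats::sd(x) / 2)
  expect_equal(unname(se2), unname(res$se))
})

test_that("cell-type correlation applies centering then spearman", {
  set.seed(18)
  g <- 150
  ids <- sprintf("g%03d", 1:g)
  delta <- structure(stats::rnorm(g), names = ids, class = "delta_profile")
  panel <- matrix(stats::rlnorm(g * 4), g, 4,
                  dimnames = list(ids, paste0("ct", 1:4)))
  rho <- celltype_correlation(delta, panel, min_shared = 100)
  centered <- panel - rowMeans(panel)
  oracle <- vapply(colnames(panel), function(ct)
    stats::cor(as.numeric(delta), centered[ids, ct], method = "spearman"),
    numeric(1))
  expect_equal(rho[names(oracle)][order(names(oracle))],
               oracle[order(names(oracle))], tolerance = 1e-10)
  expect_true(all(rho >= -1 & rho <= 1))

  expect_error(celltype_correlation(delta, panel[1:50, ], min_shared = 100),
               "insufficient")
})

test_that("rank-identical and rank-reversed panel columns score +1 and -1", {
  set.seed(19)
  g <- 120
  ids <- sprintf("g%03d", 1:g)
  delta <- structure(stats::rnorm(g), names = ids, class = "delta_profile")
  # two-column panel: after row-centering the columns are +/- delta
  panel <- cbind(pos = 10 + as.numeric(delta), neg = 10 - as.numeric(delta))
  rownames(panel) <- ids
  rho <- celltype_correlation(delta, panel, min_shared = 100)
  expect_equal(unname(rho["pos"]), 1)
  expect_equal(unname(rho["neg"]), -1)
})
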