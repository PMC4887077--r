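make_panel <- function(vals) normalize_reference(vals)

test_that("compute_delta reproduces log2 ratios against the reference blend", {
  set.seed(12)
  panel <- make_panel(matrix(stats::runif(20, 0.5, 2), 10, 2,
                             dimnames = list(paste0("g", 1:10), NULL)))
  hyper <- list(omega = c(0.4, 0.6))
  blend <- drop(panel %*% hyper$omega)

  # r equal to the blend: all-zero delta
  d0 <- compute_delta(blend, hyper, panel)
  expect_equal(as.numeric(unclass(d0)), rep(0, 10), tolerance = 1e-12)

  # doubling one gene (before renormalization is irrelevant: ratios only)
  r <- blend; r[3] <- 2 * r[3]
  d <- compute_delta(r, hyper, panel)
  expect_equal(unname(unclass(d)["g3"]), 1, tolerance = 1e-12)

  # random positive vectors match the element-wise oracle
  r2 <- stats::rgamma(10, 2); r2 <- r2 / sum(r2)
  d2 <- compute_delta(r2, hyper, panel)
  expect_equal(as.numeric(unclass(d2)), unname(log2(r2) - log2(blend)),
               tolerance = 1e-12)
})

test_that("delta is antisymmetric and scale invariant", {
  set.seed(13)
  panel <- make_panel(matrix(stats::runif(16, 0.5, 2), 8, 2))
  hyper <- list(omega = c(0.5, 0.5))
  blend <- drop(panel %*% hyper$omega)
  r <- stats::rgamma(8, 2); r <- r / sum(r)

  d <- compute_delta(r, hyper, panel)
  # swapping the roles of r and the blend flips the sign: build a panel
  # whose blend equals r by using r itself as the single reference
  panel_r <- make_panel(matrix(r, 8, 1))
  d_swap <- compute_delta(blend, list(omega = 1), panel_r)
  expect_equal(as.numeric(unclass(d_swap)), -as.numeric(unclass(d)),
               tolerance = 1e-10)

  # a common multiplicative factor cancels in the log ratio
  expect_equal(unname(log2(3 * r) - log2(3 * blend)),
               as.numeric(unclass(d)), tolerance = 1e-12)
})

test_that("rank_genes orders both directions with documented tie-breaking", {
  delta <- structure(c(3, -1, 0), names = c("gA", "gB", "gC"),
                     class = "delta_profile")
  rk <- rank_genes(delta, 1)
  expect_equal(rk$up$gene_id, "gA")
  expect_equal(rk$down$gene_id, "gB")

  rk_all <- rank_genes(delta, 3)
  expect_setequal(rk_all$up$gene_id, c("gA", "gB", "gC"))
  expect_setequal(rk_all$down$gene_id, c("gA", "gB", "gC"))
  expect_equal(rk_all$up$rank, 1:3)

  # duplicated values: stable lexicographic tie rule
  dup <- structure(c(2, 2, -2, -2, 0), names = c("gD", "gB", "gE", "gA", "gC"),
                   class = "delta_profile")
  rk2 <- rank_genes(dup, 2)
  expect_equal(rk2$up$gene_id, c("gB", "gD"))
  expect_equal(rk2$down$gene_id, c("gA", "gE"))

  expect_error(rank_genes(dup, 6), "between 1 and")
})

test_that("welch t statistics match the stats::t.test oracle", {
  set.seed(14)
  pre <- matrix(stats::rnorm(8 * 5, 10), 8, 5,
                dimnames = list(paste0("g", 1:8), NULL))
  post <- matrix(stats::rnorm(8 * 6, 10.5), 8, 6,
                 dimnames = list(paste0("g", 1:8), NULL))
  tab <- ttest_per_gene(pre, post)
  for (g in rownames(pre)) {
    oracle <- stats::t.test(pre[g, ], post[g, ])
    row <- tab[tab$gene_id == g, ]
    expect_equal(row$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, oracle$p.value, tolerance = 1e-10)
    expect_equal(row$df, unname(oracle$parameter), tolerance = 1e-10)
  }
  expect_false(is.unsorted(tab$p_value))
})

test_that("t-test handles identical and degenerate groups", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6)
  tab <- ttest_per_gene(x[, 1:3, drop = FALSE], x[, 4:6, drop = FALSE])
  expect_equal(tab$statistic, 0)
  expect_equal(tab$p_value, 1)

  # both groups constant and equal: flagged undefined, placed last
  pre <- rbind(g1 = c(5, 5, 5), g2 = c(1, 2, 3))
  post <- rbind(g1 = c(5, 5, 5), g2 = c(4, 5, 9))
  tab2 <- ttest_per_gene(pre, post)
  expect_true(tab2$undefined[tab2$gene_id == "g1"])
  expect_equal(tab2$gene_id[nrow(tab2)], "g1")

  # paired variant agrees with its oracle
  set.seed(15)
  pre <- matrix(stats::rnorm(4 * 5), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  post <- pre + matrix(stats::rnorm(4 * 5, 0.5), 4, 5)
  tabp <- ttest_per_gene(pre, post, paired = TRUE)
  for (g in rownames(pre)) {
    oracle <- stats::t.test(post[g, ], pre[g, ], paired = TRUE)
    row <- tabp[tabp$gene_id == g, ]
    expect_equal(row$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("ranking overlap equals the brute-force set intersection", {
  delta <- structure(seq(-5, 5, length.out = 30),
                     names = sprintf("g%02d", 1:30), class = "delta_profile")
  rk <- rank_genes(delta, 10)
  expect_equal(compare_rankings(rk, rk, 10), length(union(
    utils::head(rk$up$gene_id, 10), utils::head(rk$down$gene_id, 10))))

  expect_equal(compare_rankings(c("a", "b", "c"), c("x", "y", "z"), 3), 0)

  set.seed(16)
  for (i in 1:10) {
    a <- sample(sprintf("g%02d", 1:30))
    b <- sample(sprintf("g%02d", 1:30))
    k <- sample(5:15, 1)
    expect_equal(compare_rankings(a, b, k),
                 length(intersect(a[1:k], b[1:k])))
  }
})
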