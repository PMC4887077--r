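# Delta profile (per-gene log2 difference between the treatment-response
# profile and the fitted blend of references) and differential-gene ranking,
# plus the per-gene Welch t-test comparator on the original profiles.

#' Compute the delta profile
#'
#' \deqn{\delta = \log_2(r) - \log_2(\omega B)}
#' the per-gene log2 difference between the treatment-response profile and
#' the convex combination of pre-treatment profiles with the fitted weights
#' omega.  Genes with extreme delta are the candidates for up-/down-
#' regulation under treatment.  Entries of either vector below `epsilon` are
#' floored before taking logs so the delta stays finite; the number of
#' floored entries is attached as the `"floored"` attribute.
#'
#' @param x A fitted [respdecon()] object, or a `ResponseProfile`-like
#'   numeric G-vector (then `hyper` and `panel` must be given).
#' @param hyper,panel Only when `x` is a bare vector: the hyperparameter list
#'   (with `omega`) and the reference panel.
#' @param epsilon Positive floor applied before `log2`; default 1e-12.
#' @return A named numeric vector of class `delta_profile` (names = gene
#'   ids).
#' @export
compute_delta <- function(x, hyper = NULL, panel = NULL, epsilon = 1e-12) {
  if (inherits(x, "respdecon")) {
    panel <- x$state$panel
    hyper <- x$state$hyper
    r <- x$state$response
  } else {
    r <- x
    if (is.null(hyper) || is.null(panel))
      stop("hyper and panel are required when x is a bare response profile",
           call. = FALSE)
  }
  if (length(r) != nrow(panel))
    stop("response profile and panel disagree on the number of genes",
         call. = FALSE)
  stopifnot(epsilon > 0)
  blend <- drop(panel %*% hyper$omega)
  floored <- sum(r < epsilon) + sum(blend < epsilon)
  delta <- log2(pmax(r, epsilon)) - log2(pmax(blend, epsilon))
  structure(stats::setNames(delta, rownames(panel)),
            floored = floored, class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("Delta profile over %d genes: range [%.2f, %.2f] log2 units\n",
              length(x), min(x), max(x)))
  invisible(unclass(x))
}

#' Rank genes by delta
#'
#' Top-k genes in each direction of the delta profile: the up view sorted by
#' decreasing delta, the down view by increasing delta.  Equal deltas break
#' by lexicographic gene id, so rankings are reproducible.
#'
#' @param delta A [compute_delta()] profile (or named numeric vector).
#' @param k Number of genes per direction; `k = G` yields the full ordering.
#' @return A list of class `ranked_genes` with data frames `up` and `down`
#'   (columns `gene_id`, `log2_delta`, `rank`).
#' @export
rank_genes <- function(delta, k) {
  g <- length(delta)
  ids <- names(delta)
  if (is.null(ids)) stop("delta must carry gene ids as names", call. = FALSE)
  if (k < 1 || k > g)
    stop("k must be between 1 and the number of genes", call. = FALSE)
  d <- as.numeric(delta)
  up_ord <- order(-d, ids)[seq_len(k)]
  down_ord <- order(d, ids)[seq_len(k)]
  mk <- function(ord) data.frame(gene_id = ids[ord], log2_delta = d[ord],
                                 rank = seq_along(ord), row.names = NULL)
  structure(list(up = mk(up_ord), down = mk(down_ord), k = k),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, n = 10L, ...) {
  cat(sprintf("Top %d genes per direction by log2 delta\n", x$k))
  cat("Up-regulated:\n")
  print(utils::head(x$up, n))
  cat("Down-regulated:\n")
  print(utils::head(x$down, n))
  invisible(x)
}

#' Per-gene two-sample t-test on original expression profiles
#'
#' The comparator baseline: a per-gene unequal-variance (Welch) two-sample
#' t-test between the pre- and post-treatment expression matrices, ranked by
#' ascending p-value.  Genes where both groups are constant with equal means
#' have an undefined statistic; they are flagged and placed last.
#'
#' @param pre_matrix Gene x M matrix of pre-treatment expression values.
#' @param post_matrix Gene x N matrix of post-treatment expression values,
#'   same genes in the same order.
#' @param paired If `TRUE`, a paired t-test on per-gene differences
#'   (requires M == N, columns in matching order).
#' @return A data frame (one row per gene, ordered by ascending p) with
#'   columns `gene_id`, `statistic`, `df`, `p_value`, `undefined`; the test
#'   variant is recorded in the `"method"` attribute.
#' @export
ttest_per_gene <- function(pre_matrix, post_matrix, paired = FALSE) {
  pre <- as.matrix(pre_matrix); post <- as.matrix(post_matrix)
  if (nrow(pre) != nrow(post))
    stop("pre and post matrices must cover the same genes", call. = FALSE)
  ids <- rownames(pre)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(pre)))
  if (paired) {
    if (ncol(pre) != ncol(post))
      stop("paired test requires equally many pre and post columns",
           call. = FALSE)
    d <- post - pre
    n <- ncol(d)
    if (n < 2) stop("paired test needs at least 2 pairs", call. = FALSE)
    mbar <- rowMeans(d)
    s2 <- rowSums((d - mbar)^2) / (n - 1)
    tstat <- mbar / sqrt(s2 / n)
    df <- rep(n - 1, nrow(d))
    undef <- s2 == 0 & mbar == 0
    tstat[s2 == 0 & mbar != 0] <- sign(mbar[s2 == 0 & mbar != 0]) * Inf
    method <- "paired t-test"
  } else {
    n1 <- ncol(pre); n2 <- ncol(post)
    if (n1 < 2 || n2 < 2)
      stop("each group needs at least 2 samples", call. = FALSE)
    m1 <- rowMeans(pre); m2 <- rowMeans(post)
    s1 <- rowSums((pre - m1)^2) / (n1 - 1)
    s2 <- rowSums((post - m2)^2) / (n2 - 1)
    se2 <- s1 / n1 + s2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
    undef <- se2 == 0 & m1 == m2
    zero_var_diff <- se2 == 0 & m1 != m2
    tstat[zero_var_diff] <- sign((m1 - m2)[zero_var_diff]) * Inf
    df[se2 == 0] <- NA_real_
    method <- "Welch two-sample t-test"
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.infinite(tstat)] <- 0
  tstat[undef] <- NA_real_
  p[undef] <- NA_real_
  out <- data.frame(gene_id = ids, statistic = tstat, df = df, p_value = p,
                    undefined = undef, row.names = NULL)
  out <- out[order(out$undefined, out$p_value, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

#' Overlap between two top-k gene rankings
#'
#' Size of the intersection of the top-k gene sets of two rankings; used to
#' contrast the delta-profile ranking with the t-test comparator.
#'
#' @param table_a,table_b A `ranked_genes` object, a data frame with a
#'   `gene_id` column (ordered best-first), or a character vector of gene
#'   ids (ordered best-first).
#' @param k Top-k cutoff applied to both.
#' @param direction For `ranked_genes` inputs: `"up"`, `"down"`, or `"both"`
#'   (union of the two top-k views).
#' @return Integer overlap count.
#' @export
compare_rankings <- function(table_a, table_b, k, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  a <- top_gene_set(table_a, k, direction)
  b <- top_gene_set(table_b, k, direction)
  length(intersect(a, b))
}

top_gene_set <- function(x, k, direction) {
  if (inherits(x, "ranked_genes")) {
    pick <- function(df) utils::head(df$gene_id, k)
    return(switch(direction,
                  up = pick(x$up), down = pick(x$down),
                  both = union(pick(x$up), pick(x$down))))
  }
  if (is.data.frame(x)) {
    if (!"gene_id" %in% names(x))
      stop("ranked data frame needs a gene_id column", call. = FALSE)
    return(utils::head(x$gene_id, k))
  }
  utils::head(as.character(x), k)
}
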