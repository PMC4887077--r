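# Domain containers: reference panel (column-stochastic gene x M matrix of
# pre-treatment profiles) and count matrix (gene x N non-negative integer
# post-treatment profiles).  Both are plain matrices carrying a class, with
# gene ids as rownames and sample ids as colnames.

#' Normalize pre-treatment profiles into a reference panel
#'
#' Each pre-treatment expression profile is scaled so that its G entries sum
#' to 1, turning every column into a discrete probability distribution over
#' genes.  The resulting column-stochastic matrix is the reference panel
#' \eqn{B = [b_1 \ldots b_M]} against which post-treatment profiles are
#' deconvolved.
#'
#' @param x A gene x sample numeric matrix of non-negative expression values.
#'   Rownames (gene ids) and colnames (sample ids) are kept; missing dimnames
#'   are filled in with `gene_1 ...` / `ref_1 ...`.
#' @return A `reference_panel`: a column-stochastic matrix (each column sums
#'   to 1) with the input's dimnames.
#' @examples
#' b <- matrix(c(2, 2, 4, 1, 1, 2), nrow = 3)
#' normalize_reference(b)
#' @export
normalize_reference <- function(x) {
  x <- as_gene_matrix(x, prefix = "ref")
  if (anyNA(x)) stop("reference matrix contains missing values", call. = FALSE)
  if (any(x < 0)) stop("reference matrix contains negative entries", call. = FALSE)
  if (nrow(x) < 2L) stop("a reference panel needs at least 2 genes", call. = FALSE)
  cs <- colSums(x)
  if (any(cs == 0)) {
    bad <- colnames(x)[cs == 0]
    stop("degenerate reference sample(s) with all-zero expression: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(x, 2L, cs, "/")
  structure(out, class = c("reference_panel", "matrix", "array"))
}

#' Discretize post-treatment profiles into a count matrix
#'
#' The multinomial likelihood requires integer counts per gene.  Real-valued
#' profiles are rescaled so each column sums to `target_total` and rounded by
#' the largest-remainder method, which conserves the column total exactly.
#' `target_total` controls the precision with which relative expression is
#' represented (larger totals resolve smaller expression differences).
#'
#' @param x A gene x sample numeric matrix of non-negative values.
#' @param target_total Positive integer; the exact post-rounding column sum.
#'   Default `1e6` counts per sample.
#' @return A `count_matrix`: integer-valued matrix whose columns each sum to
#'   `target_total`, with a `totals` attribute of per-column sums.
#' @examples
#' p <- matrix(c(0.25, 0.75), nrow = 2)
#' discretize_counts(p, target_total = 100)
#' @export
discretize_counts <- function(x, target_total = 1e6) {
  x <- as_gene_matrix(x, prefix = "post")
  if (anyNA(x)) stop("count matrix contains missing values", call. = FALSE)
  if (any(x < 0)) stop("count matrix contains negative entries", call. = FALSE)
  target_total <- as.numeric(target_total)
  if (length(target_total) != 1L || !is.finite(target_total) ||
      target_total < 1 || target_total != floor(target_total))
    stop("target_total must be a single positive integer", call. = FALSE)
  if (target_total < nrow(x))
    warning("target_total below the number of genes; ",
            "most genes will receive zero counts")
  cs <- colSums(x)
  if (any(cs == 0)) {
    bad <- colnames(x)[cs == 0]
    stop("degenerate post-treatment sample(s) with all-zero expression: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- apply(x, 2L, largest_remainder, total = target_total)
  dimnames(out) <- dimnames(x)
  structure(out, totals = colSums(out),
            class = c("count_matrix", "matrix", "array"))
}

#' Wrap an already-integer matrix as a count matrix
#'
#' For inputs that are true counts (or gene subsets of a discretized matrix)
#' no rescaling is wanted; the observed column totals are kept as-is.
#'
#' @param x A gene x sample matrix of non-negative integers.
#' @return A `count_matrix` preserving the observed per-column totals.
#' @export
as_count_matrix <- function(x) {
  x <- as_gene_matrix(x, prefix = "post")
  if (any(x < 0) || any(x != floor(x)))
    stop("as_count_matrix() requires non-negative integer entries", call. = FALSE)
  structure(x, totals = colSums(x),
            class = c("count_matrix", "matrix", "array"))
}

# Largest-remainder rounding of a non-negative column to an exact total.
# Floors the rescaled values, then hands the remaining units to the entries
# with the largest fractional parts (ties broken by index).
largest_remainder <- function(col, total) {
  scaled <- col / sum(col) * total
  base <- floor(scaled)
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    frac <- scaled - base
    give <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  base
}

as_gene_matrix <- function(x, prefix) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0(prefix, "_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  x
}

# Hard, order-preserving gene alignment between companion matrices.
check_gene_alignment <- function(panel, counts) {
  if (nrow(panel) != nrow(counts) ||
      !identical(rownames(panel), rownames(counts)))
    stop("gene ids of the reference panel and count matrix must be ",
         "identical in content and order", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d genes x %d pre-treatment profiles (column-stochastic)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("Count matrix: %d genes x %d post-treatment profiles, totals %s\n",
              nrow(x), ncol(x),
              if (length(unique(tot)) == 1L) format(tot[1], big.mark = ",")
              else paste0(format(min(tot), big.mark = ","), "-",
                          format(max(tot), big.mark = ","))))
  invisible(x)
}
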