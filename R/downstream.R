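# Downstream statistics: clinical-outcome correlation with Bonferroni
# correction, the gene-subset sensitivity test, and the cell-type panel
# correlation of the delta profile.

#' Percent reduction of a disease-activity indicator
#'
#' `100 * (baseline - followup) / baseline`; negative when the indicator
#' worsened.  A zero baseline makes the reduction undefined: those entries
#' come back `NA` and the affected patients are dropped listwise from that
#' indicator's correlation.
#'
#' @param baseline,followup Numeric vectors (recycled to common length).
#' @return Numeric vector of percent reductions, `NA` where `baseline == 0`.
#' @examples
#' pct_reduction(c(30, 2), c(15, 1))  # both 50
#' @export
pct_reduction <- function(baseline, followup) {
  if (any(baseline < 0, na.rm = TRUE) || any(followup < 0, na.rm = TRUE))
    stop("disease-activity indicators cannot be negative", call. = FALSE)
  out <- 100 * (baseline - followup) / baseline
  out[!is.na(baseline) & baseline == 0] <- NA_real_
  out
}

#' Correlate percent treatment response with a clinical reduction
#'
#' Spearman or Pearson correlation between the model's per-patient percent
#' treatment response and a per-patient percent reduction in a clinical
#' indicator.  Pairs with a missing value on either side are dropped
#' listwise; the retained n is reported.  Two-sided p-values use the
#' standard asymptotic tests (t approximation; ties allowed for Spearman).
#'
#' @param responses Named or plain numeric vector of percent-treatment-
#'   response estimates.
#' @param reductions Numeric vector of percent reductions, same patients in
#'   the same order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `rho`, `p` (raw, uncorrected), `n`, `method`.
#' @export
correlate_outcome <- function(responses, reductions,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(responses) != length(reductions))
    stop("responses and reductions must be the same length", call. = FALSE)
  keep <- is.finite(responses) & is.finite(reductions)
  x <- responses[keep]; y <- reductions[keep]
  if (length(x) < 3)
    stop("need at least 3 complete pairs after exclusions", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one of the vectors is constant", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Bonferroni correction
#'
#' `min(1, raw_p * n_tests)`; here the family is, by default, the four
#' disease-activity indicators tested per correlation method.
#'
#' @param raw_p Raw p-value(s) in `[0, 1]`.
#' @param n_tests Family size (positive integer).
#' @return Corrected p-value(s), capped at 1.
#' @examples
#' bonferroni(0.010, 4)  # 0.040
#' @export
bonferroni <- function(raw_p, n_tests) {
  if (any(!is.na(raw_p) & (raw_p < 0 | raw_p > 1)))
    stop("raw_p must lie in [0, 1]", call. = FALSE)
  if (n_tests < 1 || n_tests != floor(n_tests))
    stop("n_tests must be a positive integer", call. = FALSE)
  pmin(1, raw_p * n_tests)
}

#' Clinical correlation table
#'
#' Correlates percent treatment response against the percent reduction of
#' each of the four disease-activity indicators (PGA, ESR, active joint
#' count, LRM joint count), by both Spearman and Pearson, with Bonferroni
#' correction over the indicator family.
#'
#' @param responses Named vector of percent-treatment-response estimates
#'   (names = patient ids matching `clinical$patient_id`).
#' @param clinical A clinical table as read by [read_clinical()]: columns
#'   `patient_id`, then `<ind>_0` / `<ind>_6` for `pga`, `esr`, `active`,
#'   `lrm`.
#' @param family_size Bonferroni family size; default 4 (one per indicator).
#' @return Data frame with one row per indicator: `indicator`,
#'   `spearman_rho`, `spearman_p_bonf`, `pearson_rho`, `pearson_p_bonf`,
#'   `n`; excluded-patient counts per indicator in the `"excluded"`
#'   attribute.
#' @export
clinical_correlations <- function(responses, clinical, family_size = 4L) {
  idx <- match(clinical$patient_id, names(responses))
  if (anyNA(idx))
    stop("clinical table contains patient ids with no response estimate: ",
         paste(utils::head(clinical$patient_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  resp <- as.numeric(responses)[idx]
  indicators <- c("pga", "esr", "active", "lrm")
  rows <- vector("list", length(indicators))
  excluded <- integer(length(indicators))
  names(excluded) <- indicators
  for (i in seq_along(indicators)) {
    ind <- indicators[i]
    red <- pct_reduction(clinical[[paste0(ind, "_0")]],
                         clinical[[paste0(ind, "_6")]])
    excluded[i] <- sum(!is.finite(red))
    sp <- correlate_outcome(resp, red, "spearman")
    pe <- correlate_outcome(resp, red, "pearson")
    rows[[i]] <- data.frame(indicator = ind,
                            spearman_rho = sp$rho,
                            spearman_p_bonf = bonferroni(sp$p, family_size),
                            pearson_rho = pe$rho,
                            pearson_p_bonf = bonferroni(pe$p, family_size),
                            n = sp$n)
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Gene-subset sensitivity test
#'
#' Assesses the robustness of the per-patient percent-treatment-response
#' estimates by partitioning the genes into `n_subsets` disjoint subsets,
#' refitting the model on each subset alone, and summarizing per-patient
#' variability as the standard error of the mean of the subset estimates
#' (SD of the `n_subsets` estimates divided by `sqrt(n_subsets)`).
#'
#' @param panel Reference panel (G x M).
#' @param counts Companion count matrix.
#' @param control [respdecon_control()] used for the full fit and every
#'   subset fit.
#' @param n_subsets Number of disjoint gene subsets; default 4.
#' @param partition `"round_robin"` (deterministic, gene index modulo
#'   `n_subsets`) or `"random"` (seeded by `control$seed`).
#' @return List of class `sensitivity_result`: `estimates` (patients x
#'   subsets matrix), `full` (full-data estimates), `se` (per-patient
#'   standard errors), `average_se`, `max_se`, `failed` (indices of subsets
#'   whose fit failed, if any).
#' @export
sensitivity_test <- function(panel, counts, control = respdecon_control(),
                             n_subsets = 4L,
                             partition = c("round_robin", "random")) {
  partition <- match.arg(partition)
  check_gene_alignment(panel, counts)
  g <- nrow(panel)
  if (g < n_subsets * 10)
    stop("too few genes for a ", n_subsets, "-subset sensitivity test",
         call. = FALSE)
  groups <- if (partition == "round_robin") {
    (seq_len(g) - 1L) %% n_subsets + 1L
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(control$seed)
    gr <- sample.int(n_subsets, g, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    gr
  }
  full_fit <- respdecon(panel, counts, control)
  full <- extract_treatment_response(full_fit)
  est <- matrix(NA_real_, nrow = ncol(counts), ncol = n_subsets,
                dimnames = list(colnames(counts),
                                paste0("subset_", seq_len(n_subsets))))
  failed <- integer(0)
  for (s in seq_len(n_subsets)) {
    keep <- groups == s
    sub_panel <- normalize_reference(unclass(panel)[keep, , drop = FALSE])
    sub_counts <- as_count_matrix(unclass(counts)[keep, , drop = FALSE])
    fit_s <- tryCatch(respdecon(sub_panel, sub_counts, control),
                      error = function(e) {
                        warning(sprintf("subset %d fit failed: %s",
                                        s, conditionMessage(e)))
                        NULL
                      })
    if (is.null(fit_s)) { failed <- c(failed, s); next }
    est[, s] <- extract_treatment_response(fit_s)
  }
  se <- apply(est, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  })
  structure(list(estimates = est, full = full, se = se,
                 average_se = mean(se, na.rm = TRUE),
                 max_se = max(se, na.rm = TRUE), failed = failed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity test over %d gene subsets, %d patients\n",
              ncol(x$estimates), nrow(x$estimates)))
  cat(sprintf("  average standard error = %.3f; maximum standard error = %.3f\n",
              x$average_se, x$max_se))
  if (length(x$failed))
    cat("  failed subsets:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Cell-type panel correlation of the delta profile
#'
#' Interprets the delta profile in terms of blood cell types: each cell
#' type's expression column is first centered by the gene-wise mean across
#' all panel columns, then Spearman-correlated with the delta profile over
#' the shared genes.  Negative coefficients suggest cell types whose blood
#' concentration decreases with response to treatment.
#'
#' @param delta A [compute_delta()] profile (named by gene id).
#' @param panel Gene x cell-type expression matrix with gene rownames and
#'   cell-type colnames.
#' @param min_shared Minimum number of shared genes required; default 100.
#' @return Named numeric vector of Spearman coefficients, sorted ascending;
#'   number of shared genes in the `"n_genes"` attribute.
#' @export
celltype_correlation <- function(delta, panel, min_shared = 100L) {
  panel <- as.matrix(panel)
  if (is.null(rownames(panel)) || is.null(names(delta)))
    stop("both delta and the cell-type panel need gene ids", call. = FALSE)
  if (anyDuplicated(colnames(panel)))
    stop("cell-type labels must be unique", call. = FALSE)
  shared <- intersect(names(delta), rownames(panel))
  if (length(shared) < min_shared)
    stop("insufficient gene overlap with the cell-type panel: ",
         length(shared), " shared genes (need >= ", min_shared, ")",
         call. = FALSE)
  d <- as.numeric(delta)[match(shared, names(delta))]
  p <- panel[shared, , drop = FALSE]
  centered <- p - rowMeans(p)
  rho <- apply(centered, 2L, function(col)
    stats::cor(d, col, method = "spearman"))
  structure(sort(rho), n_genes = length(shared))
}
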