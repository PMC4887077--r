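# Synthetic cohorts with planted ground truth.  The generative process is
# deliberately the model's own likelihood: reference profiles drawn around a
# shared template, post-treatment counts drawn multinomially from convex
# mixtures of references plus a planted treatment-response profile, and
# clinical reductions built as monotone transforms of the planted response
# weights.  Every stage of the analysis can therefore be checked against
# known truth.

#' Configuration for a synthetic cohort
#'
#' Defaults describe the standard validation cohort used throughout the
#' package: 1000 genes, 10 pre-treatment references, 12 post-treatment
#' samples of 1e5 counts each, 50 differentially expressed genes planted at
#' |log2 fold change| >= 2, and per-patient response weights uniform on
#' \[0.05, 0.5\].
#'
#' @param G,M,N Genes, pre-treatment references, post-treatment samples.
#' @param total_counts Multinomial total per post-treatment sample.
#' @param n_de_genes Number of planted differentially expressed genes.
#' @param effect_range Magnitude range (log2 units) of planted effects;
#'   each planted gene draws a magnitude uniformly from this range and a
#'   random sign.
#' @param response_range Range `[lo, hi]` of the per-patient true response
#'   weight (uniform draw).
#' @param ref_concentration Dirichlet concentration tying reference profiles
#'   to the shared template; larger = more similar references.
#' @param pair_weight Fraction of each patient's reference mass placed on
#'   their own paired reference (the rest spreads over the other
#'   references), mimicking the dominance of the matched pre-treatment
#'   profile in real cohorts.
#' @param clinical_noise SD of Gaussian noise added to the clinical
#'   reduction fractions (0 = noise-free monotone transform).
#' @param overdispersion SD (log scale) of an optional per-gene log-normal
#'   multiplier applied to each sample's mixture before counting, to test
#'   robustness under misspecification; default 0 (off, the well-specified
#'   case).
#' @param n_celltypes Number of columns of the generated cell-type panel.
#' @param seed Integer seed; all stage seeds derive from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(G = 1000L, M = 10L, N = 12L,
                          total_counts = 1e5,
                          n_de_genes = 50L,
                          effect_range = c(2, 6),
                          response_range = c(0.05, 0.5),
                          ref_concentration = 1e4,
                          pair_weight = 0.6,
                          clinical_noise = 0.2,
                          overdispersion = 0,
                          n_celltypes = 38L,
                          seed = 1L) {
  stopifnot(G >= 2, M >= 1, N >= 1, total_counts >= 1,
            n_de_genes >= 0, n_de_genes <= G,
            length(response_range) == 2L,
            response_range[1] >= 0, response_range[2] <= 1,
            response_range[1] <= response_range[2],
            ref_concentration > 0, pair_weight >= 0, pair_weight <= 1,
            clinical_noise >= 0, overdispersion >= 0)
  structure(list(G = as.integer(G), M = as.integer(M), N = as.integer(N),
                 total_counts = total_counts,
                 n_de_genes = as.integer(n_de_genes),
                 effect_range = effect_range,
                 response_range = response_range,
                 ref_concentration = ref_concentration,
                 pair_weight = pair_weight,
                 clinical_noise = clinical_noise,
                 overdispersion = overdispersion,
                 n_celltypes = as.integer(n_celltypes),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x <- pmax(x, 1e-300)
  x / sum(x)
}

#' Generate a reference panel of pre-treatment profiles
#'
#' Draws one shared template expression distribution, then M patient
#' profiles from a Dirichlet centered on the template with concentration
#' `ref_concentration`, emulating inter-patient variation around a common
#' blood transcriptome.
#'
#' @param config A [cohort_config()].
#' @return A `reference_panel` (G x M).
#' @export
gen_reference_panel <- function(config) {
  set.seed(config$seed)
  # skewed expression levels over a constant background offset: array-style
  # profiles have background signal everywhere, so no gene's expected count
  # is driven to zero in every sample
  template <- stats::rgamma(config$G, shape = 0.8) + 0.1
  template <- template / sum(template)
  cols <- vapply(seq_len(config$M),
                 function(m) rdirichlet1(config$ref_concentration * template),
                 numeric(config$G))
  dimnames(cols) <- list(paste0("gene_", seq_len(config$G)),
                         paste0("pre_", seq_len(config$M)))
  normalize_reference(cols)
}

#' Plant a treatment-response profile
#'
#' Starts from the reference blend `omega B`, multiplies the planted genes
#' by `2^effect`, and renormalizes to the simplex.  Renormalization shifts
#' every gene slightly, so the achieved per-gene log2 changes (which the
#' fitted delta profile should recover) are returned alongside the nominal
#' planted effects.
#'
#' @param panel Reference panel.
#' @param config A [cohort_config()].
#' @param omega Blend weights over references; default uniform.
#' @return List: `response` (G-simplex vector), `achieved_log2fc` (all
#'   genes), `planted_ids`, `planted_effects` (nominal log2 effects).
#' @export
gen_response_profile <- function(panel, config, omega = NULL) {
  if (is.null(omega)) omega <- rep(1 / ncol(panel), ncol(panel))
  set.seed(config$seed + 1L)
  r0 <- pmax(drop(panel %*% omega), 1e-300)
  r0 <- r0 / sum(r0)
  planted <- sort(sample.int(config$G, config$n_de_genes))
  mag <- stats::runif(config$n_de_genes, config$effect_range[1],
                      config$effect_range[2])
  sgn <- sample(c(-1, 1), config$n_de_genes, replace = TRUE)
  effects <- mag * sgn
  r <- r0
  r[planted] <- r[planted] * 2^effects
  r <- r / sum(r)
  list(response = stats::setNames(r, rownames(panel)),
       achieved_log2fc = stats::setNames(log2(r / r0), rownames(panel)),
       planted_ids = rownames(panel)[planted],
       planted_effects = stats::setNames(effects, rownames(panel)[planted]))
}

# True mixing weights: response weight uniform on response_range; of the
# remaining mass, pair_weight goes to the patient's own paired reference
# (post sample n pairs with reference ((n-1) mod M) + 1) and the rest
# spreads Dirichlet(1) over the other references.
gen_true_theta <- function(config) {
  set.seed(config$seed + 2L)
  m <- config$M; n <- config$N
  w <- stats::runif(n, config$response_range[1], config$response_range[2])
  theta <- matrix(0, n, m + 1L)
  pair <- (seq_len(n) - 1L) %% m + 1L
  for (i in seq_len(n)) {
    rest <- 1 - w[i]
    if (m == 1L) {
      theta[i, 1L] <- rest
    } else {
      others <- rdirichlet1(rep(1, m - 1L))
      theta[i, pair[i]] <- config$pair_weight * rest
      theta[i, setdiff(seq_len(m), pair[i])] <-
        (1 - config$pair_weight) * rest * others
    }
    theta[i, m + 1L] <- w[i]
  }
  list(theta = theta, pair = pair)
}

#' Draw post-treatment count profiles from the model
#'
#' Each post sample's counts are `total_counts` multinomial draws from its
#' true mixture profile `[B r] theta_n`, optionally perturbed by a per-gene
#' log-normal overdispersion multiplier.
#'
#' @param panel Reference panel.
#' @param response True response profile (G-simplex).
#' @param true_theta N x (M+1) matrix of true mixing weights.
#' @param config A [cohort_config()].
#' @return A `count_matrix` (G x N).
#' @export
gen_post_counts <- function(panel, response, true_theta, config) {
  set.seed(config$seed + 3L)
  n <- nrow(true_theta)
  counts <- matrix(0L, nrow = config$G, ncol = n,
                   dimnames = list(rownames(panel),
                                   paste0("post_", seq_len(n))))
  for (i in seq_len(n)) {
    p <- mixture_profile(panel, response, true_theta[i, ])
    if (config$overdispersion > 0) {
      p <- p * stats::rlnorm(config$G, 0, config$overdispersion)
      p <- p / sum(p)
    }
    counts[, i] <- stats::rmultinom(1L, size = config$total_counts, prob = p)
  }
  as_count_matrix(counts)
}

#' Generate a clinical table tied to the planted response weights
#'
#' Baseline disease-activity indicators (PGA, ESR, active joint count, LRM
#' joint count) are drawn from realistic ranges; the percent reduction of
#' each indicator is a monotone transform of the patient's true response
#' weight plus Gaussian noise (`clinical_noise` for the active joint count,
#' twice that for the other three, so the active-joint correlation is the
#' strongest, as in real cohorts).  Follow-up counts are back-computed and
#' rounded to valid non-negative values; at `clinical_noise = 0` the
#' active-joint percent reduction is strictly monotone in the true weight.
#'
#' @param truth A `synthetic_truth` (or any list with `true_theta`).
#' @param config A [cohort_config()].
#' @return Data frame: `patient_id`, `pga_0`, `pga_6`, `esr_0`, `esr_6`,
#'   `active_0`, `active_6`, `lrm_0`, `lrm_6`.
#' @export
gen_clinical <- function(truth, config) {
  set.seed(config$seed + 4L)
  th <- truth$true_theta
  n <- nrow(th)
  w <- th[, ncol(th)]
  # target reduction fraction, strictly monotone in w
  spread <- diff(range(w))
  f <- if (spread > 0) 0.05 + 0.90 * (w - min(w)) / spread else rep(0.5, n)
  noisy <- function(sd) pmin(0.99, pmax(0.01, f + stats::rnorm(n, 0, sd)))
  f_active <- if (config$clinical_noise == 0) f else noisy(config$clinical_noise)
  f_lrm <- noisy(2 * config$clinical_noise)
  f_pga <- noisy(2 * config$clinical_noise)
  f_esr <- noisy(2 * config$clinical_noise)

  active_0 <- sample(20:60, n, replace = n > 41)
  lrm_0 <- sample(3:20, n, replace = TRUE)
  esr_0 <- sample(10:60, n, replace = TRUE)
  pga_0 <- round(stats::runif(n, 2, 8), 1)

  active_6 <- pmax(0L, as.integer(round(active_0 * (1 - f_active))))
  if (config$clinical_noise == 0) {
    # repair integer-rounding ties so the percent reduction stays strictly
    # increasing in the true weight
    ord <- order(w)
    for (j in seq(2L, length(ord))) {
      a <- ord[j - 1L]; b <- ord[j]
      while (active_6[b] > 0 &&
             pct_reduction(active_0[b], active_6[b]) <=
             pct_reduction(active_0[a], active_6[a]))
        active_6[b] <- active_6[b] - 1L
    }
  }
  lrm_6 <- pmax(0L, as.integer(round(lrm_0 * (1 - f_lrm))))
  esr_6 <- pmax(0L, as.integer(round(esr_0 * (1 - f_esr))))
  pga_6 <- pmax(0, round(pga_0 * (1 - f_pga), 1))

  data.frame(patient_id = rownames(th) %||% paste0("post_", seq_len(n)),
             pga_0 = pga_0, pga_6 = pga_6,
             esr_0 = esr_0, esr_6 = esr_6,
             active_0 = active_0, active_6 = active_6,
             lrm_0 = lrm_0, lrm_6 = lrm_6,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a cell-type expression panel
#'
#' Noisy archetype profiles for `n_celltypes` blood cell populations over
#' the cohort's gene universe, for exercising the cell-type correlation
#' stage (labels are synthetic archetypes, not measured populations).
#'
#' @param gene_ids Character vector of gene ids.
#' @param config A [cohort_config()].
#' @return Gene x cell-type matrix with positive entries.
#' @export
gen_celltype_panel <- function(gene_ids, config) {
  set.seed(config$seed + 5L)
  g <- length(gene_ids)
  base <- stats::rlnorm(g, meanlog = 4, sdlog = 1)
  panel <- vapply(seq_len(config$n_celltypes),
                  function(ct) base * stats::rlnorm(g, 0, 1),
                  numeric(g))
  dimnames(panel) <- list(gene_ids,
                          sprintf("celltype_%02d", seq_len(config$n_celltypes)))
  panel
}

#' Simulate a complete cohort with planted ground truth
#'
#' Orchestrates the generator: reference panel, planted response profile,
#' true mixing weights, multinomial post-treatment counts, clinical table,
#' and cell-type panel, together with a `truth` record for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `panel`, `counts`, `clinical`,
#'   `celltype_panel`, `truth` (fields `true_theta`, `true_response`,
#'   `achieved_log2fc`, `planted_ids`, `planted_effects`, `pair`, `omega`,
#'   `seed`), `config`.
#' @examples
#' sim <- simulate_cohort(cohort_config(G = 100, M = 3, N = 4,
#'                                      total_counts = 1e4, seed = 2))
#' sim$panel
#' head(sim$truth$planted_ids)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- gen_reference_panel(config)
  omega <- rep(1 / config$M, config$M)
  resp <- gen_response_profile(panel, config, omega = omega)
  tt <- gen_true_theta(config)
  counts <- gen_post_counts(panel, resp$response, tt$theta, config)
  rownames(tt$theta) <- colnames(counts)
  colnames(tt$theta) <- c(colnames(panel), "treatment_response")
  truth <- list(true_theta = tt$theta,
                true_response = resp$response,
                achieved_log2fc = resp$achieved_log2fc,
                planted_ids = resp$planted_ids,
                planted_effects = resp$planted_effects,
                pair = stats::setNames(tt$pair, colnames(counts)),
                omega = omega,
                seed = config$seed)
  class(truth) <- "synthetic_truth"
  clinical <- gen_clinical(truth, config)
  celltype <- gen_celltype_panel(rownames(panel), config)
  structure(list(panel = panel, counts = counts, clinical = clinical,
                 celltype_panel = celltype, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: G=%d genes, M=%d references, ",
                     "N=%d post samples, %s counts/sample\n"),
              x$config$G, x$config$M, x$config$N,
              format(x$config$total_counts, big.mark = ",")))
  cat(sprintf("  %d planted DE genes; true response weights in [%.2f, %.2f]; seed %d\n",
              x$config$n_de_genes, min(x$truth$true_theta[, ncol(x$truth$true_theta)]),
              max(x$truth$true_theta[, ncol(x$truth$true_theta)]), x$config$seed))
  invisible(x)
}
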