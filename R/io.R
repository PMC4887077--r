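# Plain-text readers/writers and the end-to-end pipeline driver.
#
# Matrix format: tab-delimited, header row of sample ids, first column of
# unique gene ids, locale-independent numerics (period decimal separator).
# Clinical format: CSV with header patient_id, pga_0, pga_6, esr_0, esr_6,
# active_0, active_6, lrm_0, lrm_6.

#' Read a gene x sample matrix
#'
#' @param path Tab-delimited file: header row of sample ids, first column of
#'   gene ids, numeric cells.
#' @return Numeric matrix with gene rownames and sample colnames, in file
#'   order.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("matrix file needs a header and at least one gene row: ", path,
         call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  n_samples <- length(header) - 1L
  if (n_samples < 1L)
    stop("matrix header declares no sample columns: ", path, call. = FALSE)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(rows)
  bad <- which(widths != n_samples + 1L)
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s (expected %d fields, found %d)",
                 bad[1L] + 1L, path, n_samples + 1L, widths[bad[1L]]),
         call. = FALSE)
  ids <- vapply(rows, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = n_samples,
                 dimnames = list(ids, header[-1L]))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d of %s (gene %s)",
                   i + 1L, path, ids[i]), call. = FALSE)
    vals[i, ] <- v
  }
  vals
}

#' Write a gene x sample matrix
#'
#' Inverse of [read_matrix()]: tab-delimited with a `gene_id` header column.
#' Values are written with 17 significant digits, so write/read round-trips
#' are exact and identical inputs produce byte-identical files.
#'
#' @param x Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t"),
    character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read a clinical table
#'
#' @param path CSV with header `patient_id, pga_0, pga_6, esr_0, esr_6,
#'   active_0, active_6, lrm_0, lrm_6`.
#' @return Data frame with those columns; ids unique, counts non-negative.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "pga_0", "pga_6", "esr_0", "esr_6",
              "active_0", "active_6", "lrm_0", "lrm_6")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("clinical table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ids in clinical table", call. = FALSE)
  num <- df[setdiff(needed, "patient_id")]
  if (any(num < 0, na.rm = TRUE))
    stop("clinical indicators cannot be negative", call. = FALSE)
  df[needed]
}

#' Write a clinical table
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles all paths and analysis parameters for [run_pipeline()].  Stages
#' beyond the core fit run only when their inputs are supplied
#' (`clinical`, `celltype_panel`) or requested (`run_sensitivity`).
#'
#' @param reference,post Paths to the pre-/post-treatment matrices
#'   ([read_matrix()] format).
#' @param out Output directory (created if needed).
#' @param clinical Optional path to the clinical CSV.
#' @param celltype_panel Optional path to a gene x cell-type matrix.
#' @param seed Top-level seed; every stage derives its seed from it.
#' @param n_restarts,max_outer,rel_tol Fit parameters (see
#'   [respdecon_control()]).
#' @param total_counts Discretization total per post sample.
#' @param top_k Genes per direction in the ranked tables.
#' @param run_sensitivity Run the gene-subset sensitivity test.
#' @param n_subsets Subsets for the sensitivity test.
#' @param bonferroni_m Bonferroni family size for clinical correlations.
#' @param epsilon Delta-profile floor.
#' @return A list of class `run_config`.
#' @export
run_config <- function(reference, post, out,
                       clinical = NULL, celltype_panel = NULL,
                       seed = 1L, n_restarts = 10L, max_outer = 35L,
                       rel_tol = 1e-7, total_counts = 1e6, top_k = 100L,
                       run_sensitivity = FALSE, n_subsets = 4L,
                       bonferroni_m = 4L, epsilon = 1e-12) {
  structure(list(reference = reference, post = post, out = out,
                 clinical = clinical, celltype_panel = celltype_panel,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 max_outer = as.integer(max_outer), rel_tol = rel_tol,
                 total_counts = total_counts, top_k = as.integer(top_k),
                 run_sensitivity = isTRUE(run_sensitivity),
                 n_subsets = as.integer(n_subsets),
                 bonferroni_m = as.integer(bonferroni_m),
                 epsilon = epsilon),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' normalize -> discretize -> fit -> extract percent treatment response ->
#' delta profile -> gene ranking -> (optional) sensitivity test, cell-type
#' correlation, clinical correlation.  All declared outputs plus a
#' reproducibility manifest are written to `config$out`.  Identical config
#' and seed produce byte-identical theta and response outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 on success), `outputs` (named
#'   paths), `fit`, and the stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  # upfront validation: fail before any compute
  for (p in c(config$reference, config$post, config$clinical,
              config$celltype_panel))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }

  panel <- stage("normalize", normalize_reference(read_matrix(config$reference)))
  counts <- stage("discretize",
                  discretize_counts(read_matrix(config$post),
                                    target_total = config$total_counts))
  control <- respdecon_control(max_outer = config$max_outer,
                               rel_tol = config$rel_tol,
                               n_restarts = config$n_restarts,
                               seed = config$seed)
  fit <- stage("fit", respdecon(panel, counts, control))
  message(sprintf("restart log likelihoods: %s",
                  paste(sprintf("%.2f", fit$per_restart_logliks), collapse = ", ")))
  message(sprintf("converged after %d outer iterations (converged=%s)",
                  fit$iterations_used, isTRUE(fit$converged)))

  pct <- extract_treatment_response(fit)
  delta <- stage("delta", compute_delta(fit, epsilon = config$epsilon))
  message(sprintf("delta epsilon-floor hits: %d", attr(delta, "floored")))
  ranked <- stage("rank", rank_genes(delta, k = min(config$top_k, length(delta))))

  outputs <- list()
  emit <- function(name, file, writer) {
    path <- file.path(config$out, file)
    writer(path)
    outputs[[name]] <<- path
  }
  emit("theta", "theta.tsv", function(p) write_matrix(coef(fit), p))
  emit("response", "response_profile.tsv", function(p)
    write_matrix(matrix(fit$state$response,
                        dimnames = list(rownames(panel), "response")), p))
  emit("pct_response", "pct_treatment_response.tsv", function(p)
    write_matrix(matrix(pct, dimnames = list(names(pct), "pct_response")), p))
  emit("trace", "loglik_trace.tsv", function(p)
    utils::write.table(data.frame(iteration = seq_along(fit$state$loglik_trace) - 1L,
                                  loglik = sprintf("%.17g", fit$state$loglik_trace)),
                       p, sep = "\t", row.names = FALSE, quote = FALSE))
  emit("delta", "delta_profile.tsv", function(p)
    write_matrix(matrix(as.numeric(delta),
                        dimnames = list(names(delta), "log2_delta")), p))
  emit("ranked", "ranked_genes.tsv", function(p) {
    up <- cbind(ranked$up, direction = "up")
    down <- cbind(ranked$down, direction = "down")
    utils::write.table(rbind(up, down), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
  emit("gene_list", "top_genes.txt", function(p)
    writeLines(union(ranked$up$gene_id, ranked$down$gene_id), p))

  sens <- NULL
  if (config$run_sensitivity) {
    sens <- stage("sensitivity",
                  sensitivity_test(panel, counts, control,
                                   n_subsets = config$n_subsets))
    emit("sensitivity", "sensitivity.tsv", function(p) {
      df <- data.frame(patient_id = rownames(sens$estimates),
                       full = sens$full, sens$estimates, se = sens$se)
      utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    })
  }

  ct <- NULL
  if (!is.null(config$celltype_panel)) {
    ct <- stage("celltype",
                celltype_correlation(delta, read_matrix(config$celltype_panel)))
    emit("celltype", "celltype_correlation.tsv", function(p)
      utils::write.table(data.frame(cell_type = names(ct), spearman_rho = ct),
                         p, sep = "\t", row.names = FALSE, quote = FALSE))
  }

  clin <- NULL
  if (!is.null(config$clinical)) {
    clin <- stage("clinical", {
      tbl <- clinical_correlations(pct, read_clinical(config$clinical),
                                   family_size = config$bonferroni_m)
      message(sprintf("clinical exclusions per indicator: %s",
                      paste(sprintf("%s=%d", names(attr(tbl, "excluded")),
                                    attr(tbl, "excluded")), collapse = ", ")))
      tbl
    })
    emit("clinical", "clinical_correlations.tsv", function(p)
      utils::write.table(clin, p, sep = "\t", row.names = FALSE, quote = FALSE))
  }

  manifest <- c(
    sprintf("package_version: %s", as.character(utils::packageVersion("respdecon"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_restarts: %d", config$n_restarts),
    sprintf("max_outer: %d", config$max_outer),
    sprintf("rel_tol: %g", config$rel_tol),
    sprintf("total_counts: %g", config$total_counts),
    sprintf("top_k: %d", config$top_k),
    sprintf("bonferroni_m: %d", config$bonferroni_m),
    sprintf("epsilon: %g", config$epsilon),
    sprintf("input_reference: %s (md5 %s)", config$reference,
            unname(tools::md5sum(config$reference))),
    sprintf("input_post: %s (md5 %s)", config$post,
            unname(tools::md5sum(config$post))),
    sprintf("total_seconds: %.3f",
            as.numeric(Sys.time() - t_start, units = "secs")),
    sprintf("stage_seconds: %s",
            paste(sprintf("%s=%.3f", names(timings), unlist(timings)),
                  collapse = " "))
  )
  manifest_path <- file.path(config$out, "run_manifest.txt")
  writeLines(manifest, manifest_path)
  outputs$manifest <- manifest_path

  invisible(list(status = 0L, outputs = outputs, fit = fit, delta = delta,
                 ranked = ranked, sensitivity = sens, celltype = ct,
                 clinical = clin))
}

#' Write a simulated cohort as a fixture directory
#'
#' Emits the complete plain-text fixture set for a [simulate_cohort()]
#' result: reference matrix, post-treatment count matrix, clinical CSV,
#' cell-type panel, and a tab-delimited truth file (per-sample true weights
#' and pairing, per-gene true response and achieved log2 fold change).
#'
#' @param sim A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.tsv"),
             post = file.path(dir, "post_counts.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             celltype = file.path(dir, "celltype_panel.tsv"),
             truth_theta = file.path(dir, "truth_theta.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write_matrix(unclass(sim$panel), paths["reference"])
  write_matrix(unclass(sim$counts), paths["post"])
  write_clinical(sim$clinical, paths["clinical"])
  write_matrix(sim$celltype_panel, paths["celltype"])
  th <- cbind(sim$truth$true_theta, paired_reference = sim$truth$pair)
  write_matrix(th, paths["truth_theta"])
  tg <- data.frame(gene_id = names(sim$truth$true_response),
                   true_response = sim$truth$true_response,
                   achieved_log2fc = sim$truth$achieved_log2fc,
                   planted = names(sim$truth$true_response) %in%
                     sim$truth$planted_ids)
  utils::write.table(tg, paths["truth_genes"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
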