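# respdecon

Deconvolution of a shared treatment-response expression signature from
pre-/post-treatment cohorts.

## The problem

In pre/post-treatment expression studies of heterogeneous diseases (the
motivating setting is whole-blood profiling of juvenile idiopathic
arthritis patients), strong patient-specific signatures and diverse drug
regimens drown the common effect of treatment in per-gene contrasts.
`respdecon` models each post-treatment profile as a convex mixture of the
cohort's pre-treatment reference profiles plus **one hidden
treatment-response profile shared by all patients**:

```
p_n | B, r, theta_n ~ Multinomial(T_n, [B r] theta_n)
theta_n ~ Dirichlet(v)          r ~ Dirichlet(kappa * omega B)
```

where `B` is the column-stochastic gene x M reference panel, `r` the
shared response profile, and `theta_n` the patient's M+1 convex weights —
the last of which is that patient's **% treatment response**.  All
parameters are estimated by MAP via block Polak–Ribière conjugate-gradient
ascent with random restarts.  Treatment-associated genes are ranked by
the **delta profile** `delta = log2(r) - log2(omega B)`, which is also
rank-correlated against blood cell-type panels and against clinical
disease-activity reductions (with Bonferroni correction).  A synthetic
cohort generator with planted ground truth makes every stage testable.

## Worked example

```r
library(respdecon)

sim <- simulate_cohort(cohort_config(seed = 1))
sim
#> Synthetic cohort: G=1000 genes, M=10 references, N=12 post samples, 1e+05 counts/sample
#>   50 planted DE genes; true response weights in [0.11, 0.41]; seed 1

fit <- respdecon(sim$panel, sim$counts, respdecon_control(seed = 1))
fit
#> Treatment-response deconvolution (Dirichlet-multinomial mixture)
#>   1000 genes, 10 reference profiles, 12 post-treatment profiles
#>   complete log likelihood: -35017.10 (best of 10 restarts)
#>   35 outer iterations; NOT converged at rel_tol 1e-07
#>   % treatment response: median 0.563, range [0.219, 0.791]

pr <- extract_treatment_response(fit)
cor(pr, sim$truth$true_theta[, 11], method = "spearman")
#> [1] 0.986

delta <- compute_delta(fit)
rank_genes(delta, 3)
#> Top 3 genes per direction by log2 delta
#> Up-regulated:
#>    gene_id log2_delta rank
#> 1 gene_851   4.460253    1
#> 2 gene_710   4.156921    2
#> 3 gene_587   3.866442    3
#> Down-regulated:
#>    gene_id log2_delta rank
#> 1 gene_873  -1.657994    1
#> 2 gene_288  -1.339496    2
#> 3 gene_720  -1.203637    3

names(pr) <- sim$clinical$patient_id
clinical_correlations(pr, sim$clinical)
#>   indicator spearman_rho spearman_p_bonf pearson_rho pearson_p_bonf  n
#> 1       pga    0.3006993    1.0000000000   0.3976402   0.8020864490 12
#> 2       esr    0.4028027    0.7768066777   0.3542039   1.0000000000 12
#> 3    active    0.8947423    0.0003402728   0.9059424   0.0001976755 12
#> 4       lrm    0.5151635    0.3460797509   0.6310030   0.1111561235 12
```

Reading the output: each patient's % treatment response is the weight
their post-treatment profile places on the shared response profile; here
the estimates rank-match the planted truth at Spearman 0.986, the top
up-regulated genes are planted DE genes, and — by construction of the
generated clinical table — the % reduction in active joint count is the
indicator that correlates with the estimates (corrected p ≈ 3e-4), while
the other three indicators stay non-significant.  Fold changes are log2
units.  Estimated *absolute* weights run about twice the planted values
(a known prior-resolved ridge, see the vignette); conclusions are
therefore stated in rank terms.

Beyond the basics: `sensitivity_test()` refits on four disjoint gene
subsets and reports per-patient standard errors; `celltype_correlation()`
interprets the delta profile against a cell-type expression panel;
`ttest_per_gene()` is the conventional per-gene Welch baseline;
`run_pipeline()` drives everything from files on disk and writes a
reproducibility manifest.  The methods vignette
(`vignettes/treatment-response-deconvolution.Rmd`) documents the model,
the optimizer, all defaults, and known limitations.

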