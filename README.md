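# llnet

Integrative analysis of blood transcriptomics, genome-wide genotypes and
serum lipids: from raw technical replicates to a directed network that
says whether lipid levels drive gene-module expression or the other way
round.

The package is aimed at statistical geneticists and systems biologists
working with population cohorts that carry expression arrays, SNP
genotypes and quantitative traits for the same individuals. It
implements, as tested R functions:

* **QC and normalization** — replicate-correlation gates (Pearson ≥ 0.94,
  Spearman ≥ 0.60), bead-weighted replicate combination
  δ = (b₁S₁ + b₂S₂)/(b₁ + b₂), quantile normalization, probe filters,
  genotype gates (call rate > 0.95, MAF > 0.01, exact Hardy–Weinberg
  P > 1e-6), and population-outlier detection by PCA with Tracy–Widom
  significant components and an 8-sd rule.
* **Trait standardization** — per-sex Anderson–Darling test, Box–Cox by
  profile maximum likelihood when needed, Z-scores.
* **Association** — per-probe OLS of a trait on expression with
  covariates and Bonferroni control, and the joint "meta-lipid" model
  Y = XB + E over all seven lipids tested with Wilks' lambda
  Λ = det(E)/det(E + H) (Rao's F).
* **Co-expression networks** — soft-threshold adjacency |cor|^β with β
  chosen by the signed scale-free criterion (R² > 0.80), topological
  overlap, average-linkage clustering with branch-persistence module
  detection, SVD module eigengenes, module merging at dissimilarity 0.20,
  Spearman module–trait tests at the extrapolated module-count alpha
  (e.g. 23 modules/1000 probes → 814.637 → 6.14e-5), kME vs gene
  significance, and pairwise replication testing.
* **eQTL scans** — cis (≤ 1 Mb) linear regressions with permutation
  calibration (empirical P from the per-probe minimum P over 10,000
  permutations), trans (> 5 Mb or other chromosome) Spearman tests at
  5.0e-7, and module-level multivariate tests.
* **Causal edge orienting** — ML structural equation models over anchored
  quartets (M_A, A, B, M_B); the LEO.NB.OCA score
  log₁₀[P(causal model)/P(best rival)] with rivals reactive, confounded
  and two collider variants; gates |Pearson| > 0.3, LEO ≥ 0.3,
  path |Z| > 1.96.
* **A synthetic cohort generator** with planted modules, cis-eQTLs,
  causal topologies and corrupted replicates, plus a ground-truth record,
  so every stage is validated by parameter recovery.

## Worked example

```r
library(llnet)

ds  <- simulate_dataset(sim_config(seed = 2))   # 518 samples x 1000 probes
res <- run_pipeline(ds, top_fraction = 1, n_perm = 1000, seed = 2)

res$soft_power
#> [1] 6
print(res$modules)
#> <module_set> 924 probes, 7 modules (673 background)
a <- res$modules$assignment
mclust::adjustedRandIndex(a, ds$truth$module_assignment[names(a)])
#> [1] 0.9649235
head(dplyr::filter(res$module_trait, significant), 3)
#> # A tibble: 3 x 5
#>   module trait    rho  p_value significant
#>   <chr>  <chr>  <dbl>    <dbl> <lgl>
#> 1 ME1    HDL    0.451 5.01e-26 TRUE
#> 2 ME1    APOB  -0.371 1.70e-17 TRUE
#> 3 ME1    TG     0.503 5.59e-33 TRUE
dplyr::filter(res$orientation$edges, verdict == "causal")$edge
#> [1] "TG->module"  "module->HDL"
```

Starting from the raw replicate layers (924 of 1000 probes survive the
annotation filters), the run recovers the six planted modules almost
perfectly — adjusted Rand index 0.965, with the only confusion being 11
background probes absorbed into a small spurious cluster — and module
ME1 carries the planted lipid signature with its planted signs: HDL
positive, APOB negative, TG strongest. The orienting stage reads both
planted causal directions off the data: triglycerides drive module
expression (the generator's default topology makes TG a parent of the
module factor, LEO score 2.82) and module expression drives HDL (HDL is
generated as a child of the factor, LEO 1.29). Fitted objects expose
broom-style accessors (`tidy()`, `glance()`), and `plot_module_trait()`,
`plot_scale_free()`, `plot_kme_gs()` and `plot_ma()` draw the standard
diagnostics.

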