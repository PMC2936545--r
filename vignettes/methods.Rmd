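---
title: "Models and methods behind llnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind llnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llnet)
```

llnet implements an integrative analysis of whole-blood gene expression,
genome-wide genotypes and fasting serum lipid measures: quality control and
normalization, trait–expression association (single traits and a joint
"meta-lipid" response), weighted co-expression module detection with
eigengene summaries, permutation-calibrated eQTL scans, and structural
equation modelling (SEM) with genetic anchors to orient edges between
traits and module expression. This vignette explains each model, the
parameters that matter, and the design decisions taken where more than one
reasonable choice existed.

## The synthetic cohort

Real cohorts of this kind (hundreds of genotyped adults with replicated
blood transcriptomes and lipid panels) cannot be redistributed, so the
package carries a generator, `simulate_dataset()`, whose defaults describe
the study conditions the pipeline is meant for:

* **518 individuals** (46% male), ages 25–74, with seven lipid traits
  (TC, LDL, HDL, APOA1, APOB, TG, FFA) drawn so that each sex's mean and
  standard deviation match the clinical moments built into
  `default_trait_specs()` — e.g. total cholesterol 5.11 (0.95) mmol/L
  overall. Medication covariates are Bernoulli with prevalence 20.5%
  (hypertension medication) and 14.3% (cholesterol-lowering medication);
  age and alcohol intake are independent of the traits unless the
  `confound_age` switch is set.
* **1000 probes** on two synthetic 100-Mb autosomes, of which 240 form six
  planted co-expression modules (sizes 60…25). Module probes follow a
  single-factor model: probe = baseline + loading × factor + noise, with
  loadings uniform on [0.6, 1] and unit noise, giving realistic
  within-module correlations of roughly 0.25–0.5. Background probes are
  independent noise — the one structural feature of real expression data
  (weak pervasive correlation among "background" genes) the generator does
  not emulate, so passing recovery tests demonstrate behaviour under
  clean separation, not robustness to correlated background.
* **Technical replicates**: each sample's expression is emitted twice on
  the linear scale with log-normal technical noise (sd 0.1 on the log2
  scale) and integer bead counts uniform on [10, 60]; a 5% fraction of
  samples has the second replicate's noise inflated tenfold, which is what
  the replicate-correlation QC gates are meant to catch.
* **Genotypes** are independent Hardy–Weinberg draws (no linkage
  disequilibrium — a stated non-goal) at minor allele frequencies uniform
  on [0.05, 0.5]. Eight cis-eQTL SNPs are placed within 100 kb of their
  target probe's midpoint and shift it by `cis_effect` (0.8) noise-sd
  units per minor allele.
* **A causal topology** ties the designated trait (TG by default) to
  module 1's latent factor through one of four structures — `causal`
  (trait → factor), `reactive` (factor → trait), `confounded` (both load
  0.5 on a shared latent), `independent` — with one anchor SNP per node
  explaining 10% of its variance. These are the scenarios the
  edge-orienting stage is validated against.

Everything is a pure function of the configuration's `seed`, so the
expression, genotype and trait views drawn from the same configuration are
mutually consistent and bit-reproducible.

## Quality control and normalization

Replicate pairs are compared after log2 transformation and quantile
normalization of all replicate arrays together; a sample is dropped when
its Pearson correlation falls below 0.94 or its Spearman correlation below
0.60 (`qc_replicates()`), and MA coordinates are available for visual
checks (`replicate_ma()`, `plot_ma()`). Surviving pairs are combined by a
bead-weighted mean, \(\delta_p = (b_{1p}S_{1p} + b_{2p}S_{2p}) /
(b_{1p} + b_{2p})\): weighting by bead counts and renormalizing leaves all
downstream correlation and regression statistics invariant to the overall
scale, which an unnormalized weighted sum would not.

`quantile_normalize()` forces every sample onto the cross-sample mean
quantile vector, giving ties the mean of the pooled quantiles; it is
idempotent to machine precision. Strip-level grouping is available via
`groups` (the synthetic data has no strip structure, so the default
normalizes the whole matrix at once). Probes are kept only if autosomal,
not complementary to erythrocyte globin cDNA, and uniquely mapped
(`filter_probes()`).

SNPs pass QC when call rate > 0.95, MAF > 0.01 and Hardy–Weinberg exact
P > 1e-6 (`qc_genotypes()`); the HWE test is the exact conditional test
(the convention for genotyping QC, safe at MAF boundaries), implemented
directly and verified against full enumeration. Samples with call rate
below 0.95, or named on an external exclusion list (fingerprint and
relatedness checks are upstream concerns), are removed first.

Population outliers are found by PCA on LD-damped dosages: each SNP is
residualized on its two predecessors on the same chromosome, standardized,
and the samples decomposed; components count as significant while their
Tracy–Widom P value is below 0.01, and samples beyond 8 standard
deviations on any significant component are flagged, in a single pass
(`pca_outliers()`). The Tracy–Widom (order 1) tail probability uses
Chiani's shifted-gamma approximation (shape 46.446, scale 0.18605, shift
9.848), accurate to about 1e-3 in CDF — ample at a 0.01 gate. Note the
8-sd rule can only flag a subpopulation much smaller than the sample,
since a large aberrant group inflates the component variance it sits on.

Traits are handled within sex: an Anderson–Darling test at P < 0.01
triggers a Box–Cox power transform whose exponent is estimated by profile
maximum likelihood over [-5, 5] (a continuous optimizer, checked against a
grid search), and the possibly-transformed values are standardized to
Z-scores per sex and recombined (`transform_trait()`). Estimating the
exponent separately per sex follows directly from treating the sexes as
separate distributions; nonpositive values raise an error telling the user
to shift or exclude, rather than silently shifting.

## Association models

For a single trait, `fit_trait_expression()` regresses the trait Z-score
on a probe's log2 expression plus the trait's covariates and reports the
expression slope with 95% CI, nominal P, and Bonferroni-corrected P over
the number of probes tested; the significance gate is 0.05/m (with
m = 35,419 probes this is nominal P < 1.41e-6). Sex enters through the
prior per-sex standardization, not as a covariate. The regression
direction is trait ~ expression by default (matching the covariate
structure), with the reverse available by flag.

The "meta-lipid" model (`fit_meta_lipids()`) treats all lipid Z-scores as
a joint multivariate response \(Y = XB + E\) and tests the expression term
with Wilks' lambda, \(\Lambda = \det(E)/\det(E+H)\), where \(H\) is the
extra cross-product from dropping the term (type-III). P values use Rao's
F approximation, exact when the response or hypothesis dimension is at
most 2; with one response the test collapses to the ordinary F test, which
is verified to 1e-10. Cross-trait covariance is what buys power: a signal
spread over several correlated lipids can be jointly significant when no
single-trait test is.

Cell-type composition is handled by covariates: each marker probe is
standardized across samples and averaged within its cell-type set
(`celltype_covariates()`); adding these restores nominal type-I error in
a simulation where a latent cell fraction drives both trait and
expression.

Rank association uses Spearman's coefficient with midranks and the
t-statistic \(\rho\sqrt{(n-2)/(1-\rho^2)}\) on n−2 df — appropriate at
these sample sizes and identical to a Pearson t-test on ranks.

## Network construction and modules

The network stage takes the top 10% of probes by meta-lipid P value
(ties broken by probe id, probes collapsible to unique gene signals),
builds the all-against-all Pearson correlation matrix, and raises its
absolute values to a soft power \(\beta\): an unsigned network, since
modules are expected to contain both positively and negatively
trait-correlated members. \(\beta\) is the smallest power whose signed
scale-free fit exceeds 0.80 — the smallest qualifying power also maximizes
connectivity among qualifiers, honouring both published selection
criteria. The signed fit bins connectivity into 10 equal-width bins and
regresses log10 frequency on log10 mean connectivity, negating the R² when
the slope is positive.

Dissimilarity is 1 − TOM by default (the topological overlap matrix,
which denoises adjacency by shared neighbourhoods); 1 − adjacency is
available. Probes are clustered by average linkage. For module extraction
the package uses a **branch-persistence rule** rather than a fixed cut
height: a branch with at least 10 leaves becomes a module when the gap
between the height at which it completes and the height at which it is
absorbed covers at least 70% of its remaining headroom,
\((h_{join} - h_{branch})/(1 - h_{branch}) \ge 0.7\). The reason is
practical: with TOM dissimilarities the background coalesces in a dense
shelf of merges just below the maximum, and the shelf's position moves
with the chosen power — any constant height (absolute, quantile-based, or
proportional to the maximum) that works at one power fails at another,
whereas branch persistence separates planted modules from background
across those regimes — the test suite exercises planted-structure
recovery, probe-order invariance and the no-structure null. A classical
constant-height cut remains available through `cut_height` for users who
want it.
Everything else is conventional: modules are labelled by decreasing size,
leftover probes are background (label 0), and detection is invariant to
probe order.

A module's **eigengene** is the first right-singular vector of its
standardized submatrix, scaled to unit variance and oriented so its mean
correlation with member probes is positive (the singular vector's sign is
arbitrary; some convention is required and this one makes "high eigengene
= high member expression"). Modules whose eigengenes cluster below
dissimilarity 0.20 (correlation above 0.8) are merged and eigengenes
recomputed, iterating to a fixed point so the operation is idempotent
(`merge_modules()`).

Module–trait association uses the Spearman t-test per (eigengene, trait)
pair. Because modules are detected on a subset, the significance level is
set by extrapolating the module count to the full probe set:
23 modules in 1000 probes extrapolates to 23 × 35419/1000 = 814.637
modules, hence alpha 0.05/814.637 = 6.14e-5
(`extrapolate_module_alpha()`). Module membership (kME, correlation with
the eigengene) versus gene significance (absolute trait correlation)
summarizes whether hub genes carry the association; replication in an
independent expression matrix tests all core-gene pairs at a Bonferroni
gate of 0.05/21 = 2.38e-3 for seven genes.

## eQTL scans

A SNP is **cis** to a probe within 1 Mb of its midpoint and **trans**
beyond 5 Mb or on another chromosome; the 1–5 Mb band belongs to neither
scan (the definitions leave a gap, and assigning it to either would
contradict one of them). cis associations use simple linear regression on
minor-allele dosage, with significance calibrated by permutation: the
probe's best cis P value is compared with its distribution over
permutations of expression relative to genotype, empirical
P = (1 + #{permutation min-P ≤ observed})/(B + 1), gated at 0.05. The
per-probe min-P statistic (rather than per-SNP permutation) controls for
the number and correlation of cis SNPs per probe; the +1 correction keeps
the empirical P away from zero. The default B = 10,000; the permutation
stream is seeded and vectorized, and tests in this package use a few
hundred permutations where only calibration, not resolution, is at stake.
trans associations use the Spearman t-test at a fixed genome-wide
threshold of 5.0e-7, the analytic shortcut that replaces genome-wide
permutation. Module-level tests regress all module probes jointly on a
SNP's dosage and use the same Wilks' lambda machinery.

## SEM edge orienting

The causal stage asks, for an edge between nodes A and B (a trait and a
module eigengene, or two traits), which direction the data support, using
genetic anchors: a SNP robustly associated with a node can only be a
cause, never an effect. With anchors \(M_A\) and \(M_B\), five path
models over \((M_A, A, B, M_B)\) are fitted by maximum likelihood
(`fit_sem()` minimizes \(F = \log\det\Sigma(\theta) +
\mathrm{tr}(S\Sigma^{-1}(\theta)) - \log\det S - p\); chi-square
= (n−1)F at the minimum, df = moments − free parameters, residual
variances on the log scale, convergence tolerance 1e-10 on F, standard
errors from the inverse information):

1. causal: \(M_A \to A \to B \gets M_B\)
2. reactive: \(M_A \to A \gets B \gets M_B\)
3. confounded: \(M_A \to A\), \(M_B \to B\), free residual covariance
   between A and B standing in for a shared hidden cause
4. collider on A: both anchors feed A, \(A \to B\)
5. collider on B: both anchors feed B, \(B \to A\)

The confounder is parameterized through a residual covariance rather than
an explicit unit-variance latent with two free loadings because the latent
version is not identified from four observed variables (only the loading
product enters the implied covariance), which distorts its fit P value
and, through it, the score below.

The **LEO.NB.OCA score** is the log10 ratio of the causal model's fit P
to the best (largest) rival P. A score of 0.3 means the causal model fits
at least twice as well as every alternative and declares the orientation;
the edge itself must first pass an absolute Pearson correlation of 0.3,
the fitted A→B path must have |Z| > 1.96, and a causal-model fit P at or
below 0.05 flags the model as a poor absolute fit even when it is the
best on offer. In the package's validation simulations (n = 500, anchors
explaining 10% of node variance), a true causal path of 0.5 is oriented
correctly in well over 80% of replicates, while confounded pairs (shared
latent, arms 0.5) exceed the 0.3 threshold in roughly 5–6% of
orientation tests — around, and in this weak-confounding regime slightly
above, the nominal 5% bound, because the score's false positives are
exactly the replicates where the true confounder model's fit P happens
to fall below half the causal model's. Note that the two directions of
one edge are mutually exclusive at
this threshold — each direction's rival set contains the opposite causal
model — so quoting a per-edge "either direction" rate doubles the
per-test rate by construction.

Anchors can be auto-selected per node, greedily (best nominal P) or by
forward-stepwise regression (add SNPs while the partial-F P stays below
0.05), with a cross-assignment check that a SNP associates most strongly
with the node it anchors (`anchor_autoselect()`); the pipeline driver
additionally enforces one distinct SNP per node, since the score requires
orthogonal anchors and collinear anchors are rejected outright.

## The pipeline driver and reproducibility

`run_pipeline()` chains the stages in study order — replicate QC,
combination, quantile normalization, probe filtering, genotype QC, PCA
outliers, trait standardization, meta-lipid association, probe selection,
soft-power selection, module detection and merging, module–trait
correlation at the extrapolated alpha, permutation-calibrated cis and
trans scans for the lead (most trait-associated) module, module-level
eQTL tests, and edge orienting of the lead eigengene against its top two
traits. Every exclusion is recorded with a reason, and the returned
manifest carries the seed, a parameter hash and a result hash, so a rerun
with identical inputs is verifiably identical. Readers and writers
round-trip all containers through plain text (TSV, VCF, JSON);
matrices are written with 17 significant digits so doubles survive the
round trip exactly.

## Problem sizes used in validation

The bundled tests run the full stack at the default study scale (518
samples × 1000 probes) for network recovery and soft-power checks, and
use reduced scales elsewhere — a few hundred samples for regression and
SEM checks, 199–999 permutations where only calibration is at stake,
500 confounded quartets for the false-positive bound, 1000 replicates for
null-uniformity checks — sizes chosen so each check has the power it
needs. The acceptance script re-estimates the LEO false-positive rate
from 1500 fresh confounded quartets of 500 samples each.

## Known limitations

* The generator's background probes are independent; real arrays show
  weak pervasive correlation, which makes module detection harder than
  our null tests suggest.
* Genotypes carry no linkage disequilibrium, so the LD-residualization
  step of the PCA is exercised only mechanically.
* The branch-persistence threshold (0.7) was validated on the generator's
  regimes; strongly nested module structure (modules inside modules) may
  need the constant-height cut or a different threshold.
* The SEM machinery handles recursive path models over a handful of
  observed variables with at most one latent; it is a purpose-built
  orienting engine, not a general SEM package.
* Rao's F for Wilks' lambda is approximate for response dimension above
  2 with multi-df hypotheses; all uses here have a 1-df hypothesis term,
  where the approximation is exact.
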