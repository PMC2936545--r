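#' Lipid trait specifications for the simulated cohort
#'
#' Default per-trait moments used by [sim_config()]: overall and sex-specific
#' means and standard deviations for the seven serum lipid measures (total
#' cholesterol, LDL and HDL cholesterol, apolipoproteins A1 and B,
#' triglycerides and free fatty acids), on their clinical scales (mmol/L or
#' g/L).
#'
#' @return A tibble with columns `name`, `mean`, `sd`, `male_mean`,
#'   `male_sd`, `female_mean`, `female_sd`.
#' @export
default_trait_specs <- function() {
  tibble::tribble(
    ~name,   ~mean, ~sd,  ~male_mean, ~male_sd, ~female_mean, ~female_sd,
    "TC",     5.11, 0.95, 5.09,       0.95,     5.13,         0.95,
    "LDL",    3.07, 0.84, 3.17,       0.84,     2.98,         0.83,
    "HDL",    1.48, 0.36, 1.34,       0.30,     1.61,         0.36,
    "APOA1",  1.63, 0.28, 1.53,       0.25,     1.72,         0.28,
    "APOB",   0.92, 0.21, 0.95,       0.21,     0.89,         0.20,
    "TG",     1.15, 0.64, 1.27,       0.78,     1.04,         0.47,
    "FFA",    0.36, 0.21, 0.33,       0.20,     0.38,         0.22
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_dataset()] and the individual generators. Defaults emulate the
#' cohort the pipeline was designed around: 518 unrelated adults with
#' whole-blood expression, genome-wide genotypes and seven fasting lipid
#' measures, a handful of tightly co-expressed gene modules of which one (the
#' first) carries the lipid signal, planted cis-eQTLs, and SNP anchors wired
#' into a chosen causal topology between the lipid trait and the module's
#' latent factor.
#'
#' @param n_samples Number of individuals.
#' @param n_probes Number of expression probes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of module sizes (each >= 10, summing to
#'   at most `n_probes`).
#' @param module_factor_sd Standard deviation of each module's latent factor.
#' @param noise_sd Standard deviation of probe-level noise (log2 scale).
#' @param loading_range Range of per-probe loadings on the module factor,
#'   drawn uniformly.
#' @param n_snps Number of SNPs.
#' @param maf_range Interval of minor allele frequencies, within (0, 0.5].
#' @param cis_effect Planted cis-eQTL per-minor-allele shift, in units of
#'   `noise_sd` on the log2 expression scale.
#' @param n_cis_eqtl Number of planted cis-eQTLs.
#' @param trait_specs Tibble of per-trait moments; see [default_trait_specs()].
#' @param trait_loadings Traits x modules loading matrix for the standardized
#'   trait cores; rows must sum (in squares) to at most 1. Default loads HDL
#'   (+0.4) and APOB (-0.4) on module 1.
#' @param topology_trait Name of the trait wired into `causal_topology`
#'   against module 1's factor.
#' @param causal_topology One of `"causal"` (trait is a parent of the module
#'   factor), `"reactive"` (a child), `"confounded"` (both load on a shared
#'   latent), `"independent"`.
#' @param topology_path Standardized path coefficient of the topology edge
#'   (each confounder arm for `"confounded"`).
#' @param anchor_r2 Fraction of node variance explained by its anchor SNP.
#' @param htm_prevalence,cm_prevalence Prevalence of hypertension and
#'   cholesterol-lowering medication use.
#' @param male_fraction Probability a simulated individual is male.
#' @param replicate_tech_sd Technical noise sd (log2 scale) of each replicate.
#' @param corrupt_fraction Fraction of samples whose second replicate has its
#'   technical noise inflated tenfold (exercises replicate QC).
#' @param flagged_fraction Fraction of background probes flagged as
#'   non-autosomal, globin-complementary or multi-mapping (a third each).
#' @param confound_age If `TRUE`, traits receive an age component.
#' @param n_chromosomes,chrom_length Synthetic genome layout (defaults: two
#'   chromosomes of 100 Mb).
#' @param seed Integer RNG seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 518,
                       n_probes = 1000,
                       n_modules = 6,
                       module_sizes = c(60, 50, 40, 35, 30, 25),
                       module_factor_sd = 1,
                       noise_sd = 1,
                       loading_range = c(0.6, 1),
                       n_snps = 300,
                       maf_range = c(0.05, 0.5),
                       cis_effect = 0.8,
                       n_cis_eqtl = 8,
                       trait_specs = default_trait_specs(),
                       trait_loadings = NULL,
                       topology_trait = "TG",
                       causal_topology = c("causal", "reactive",
                                           "confounded", "independent"),
                       topology_path = 0.5,
                       anchor_r2 = 0.1,
                       htm_prevalence = 0.205,
                       cm_prevalence = 0.143,
                       male_fraction = 240 / 518,
                       replicate_tech_sd = 0.1,
                       corrupt_fraction = 0.05,
                       flagged_fraction = 0.10,
                       confound_age = FALSE,
                       n_chromosomes = 2,
                       chrom_length = 1e8,
                       seed = 1L) {
  causal_topology <- match.arg(causal_topology)
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) != n_modules)
    stop("`module_sizes` must have length `n_modules`", call. = FALSE)
  if (n_modules > 0 && any(module_sizes < 10))
    stop("each module must have at least 10 probes", call. = FALSE)
  if (sum(module_sizes) > n_probes)
    stop("sum(module_sizes) exceeds n_probes", call. = FALSE)
  if (module_factor_sd <= 0 || noise_sd < 0 || replicate_tech_sd <= 0)
    stop("standard deviations must be positive", call. = FALSE)
  if (any(trait_specs$sd <= 0) || any(trait_specs$male_sd <= 0) ||
      any(trait_specs$female_sd <= 0))
    stop("trait standard deviations must be positive", call. = FALSE)
  for (p in c(htm_prevalence, cm_prevalence, corrupt_fraction,
              flagged_fraction, male_fraction))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  if (!topology_trait %in% trait_specs$name)
    stop("`topology_trait` not found in `trait_specs`", call. = FALSE)

  if (is.null(trait_loadings)) {
    trait_loadings <- matrix(0, nrow(trait_specs), max(n_modules, 1),
                             dimnames = list(trait_specs$name, NULL))
    if (n_modules > 0) {
      if ("HDL" %in% trait_specs$name) trait_loadings["HDL", 1] <- 0.4
      if ("APOB" %in% trait_specs$name) trait_loadings["APOB", 1] <- -0.4
    }
  } else {
    trait_loadings <- as.matrix(trait_loadings)
    if (nrow(trait_loadings) != nrow(trait_specs))
      stop("`trait_loadings` needs one row per trait", call. = FALSE)
    rownames(trait_loadings) <- trait_specs$name
    if (any(rowSums(trait_loadings^2) > 1))
      stop("squared trait loadings must sum to at most 1 per trait",
           call. = FALSE)
  }

  structure(list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_modules = as.integer(n_modules), module_sizes = module_sizes,
    module_factor_sd = module_factor_sd, noise_sd = noise_sd,
    loading_range = loading_range, n_snps = as.integer(n_snps),
    maf_range = maf_range, cis_effect = cis_effect,
    n_cis_eqtl = as.integer(n_cis_eqtl), trait_specs = trait_specs,
    trait_loadings = trait_loadings, topology_trait = topology_trait,
    causal_topology = causal_topology, topology_path = topology_path,
    anchor_r2 = anchor_r2, htm_prevalence = htm_prevalence,
    cm_prevalence = cm_prevalence, male_fraction = male_fraction,
    replicate_tech_sd = replicate_tech_sd,
    corrupt_fraction = corrupt_fraction,
    flagged_fraction = flagged_fraction, confound_age = confound_age,
    n_chromosomes = as.integer(n_chromosomes), chrom_length = chrom_length,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# standardize a vector to unit empirical variance (mean untouched callers'
# responsibility); degenerate vectors pass through as zeros
.std <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate a complete expression-genotype-trait dataset
#'
#' The canonical generator: one seeded stream produces the probe layout and
#' planted modules, HWE genotypes with planted cis-eQTLs and causal-anchor
#' SNPs, the causal topology between the designated lipid trait and module
#' 1's latent factor, the log2 expression matrix with technical replicate
#' pairs and bead counts, the trait table with covariates, and a ground-truth
#' record for recovery tests.
#'
#' Module probes follow a single-factor model (probe = baseline + loading x
#' factor + noise) with loadings drawn uniformly from
#' `config$loading_range`; background probes are independent noise. A
#' configurable subset of background probes carries non-autosomal, globin or
#' multi-mapping annotation flags so that probe filtering can be exercised
#' without destroying planted structure.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with elements `expression`
#'   (class `expression_dataset`: `log2` probes x samples matrix,
#'   `annotation` tibble, `replicates` list with linear-scale signal matrices
#'   `S1`, `S2`, bead counts `b1`, `b2` and the `corrupted` flag),
#'   `genotypes` (class `genotype_dataset`: samples x SNPs `dosage` matrix
#'   and `info` tibble with 1-based positions), `traits` (tibble), and
#'   `truth` (class `ground_truth`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_probes

  ## ---- probe layout, module assignment, loadings -------------------------
  probe_id <- sprintf("probe_%04d", seq_len(p))
  chrom <- sample(config$n_chromosomes, p, replace = TRUE)
  pos <- round(runif(p, 1, config$chrom_length))
  assignment <- integer(p)
  if (config$n_modules > 0) {
    picked <- sample.int(p, sum(config$module_sizes))
    assignment[picked] <- rep(seq_len(config$n_modules),
                              times = config$module_sizes)
  }
  loadings <- runif(p, config$loading_range[1], config$loading_range[2])
  loadings[assignment == 0] <- 0

  # annotation flags live on background probes only
  background <- which(assignment == 0)
  n_flag <- round(config$flagged_fraction * length(background))
  flagged <- sample(background, n_flag)
  grp <- rep(1:3, length.out = n_flag)
  chrom_lab <- as.character(chrom)
  chrom_lab[flagged[grp == 1]] <- "X"
  globin <- rep(FALSE, p); globin[flagged[grp == 2]] <- TRUE
  n_map <- rep(1L, p); n_map[flagged[grp == 3]] <- 2L
  annotation <- tibble::tibble(
    probe_id = probe_id, chromosome = chrom_lab, position = pos,
    globin = globin, n_mappings = n_map)

  ## ---- SNP layout and genotypes ------------------------------------------
  snp_id <- sprintf("snp_%04d", seq_len(config$n_snps))
  snp_chrom <- sample(config$n_chromosomes, config$n_snps, replace = TRUE)
  snp_pos <- round(runif(config$n_snps, 1, config$chrom_length))
  n_cis <- min(config$n_cis_eqtl, config$n_snps)
  cis_targets <- integer(0)
  if (n_cis > 0) {
    eligible <- which(chrom_lab != "X" & !globin & n_map == 1L)
    cis_targets <- sample(eligible, n_cis)
    snp_chrom[seq_len(n_cis)] <- chrom[cis_targets]
    snp_pos[seq_len(n_cis)] <- pmax(
      1, pos[cis_targets] + round(runif(n_cis, -1e5, 1e5)))
  }
  maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(
    rbinom(n * config$n_snps, 2L, rep(maf, each = n)),
    nrow = n, dimnames = list(sprintf("sample_%03d", seq_len(n)), snp_id))

  # anchor SNPs for the causal topology, appended after the scan SNPs
  anchors <- c("anchor_trait", "anchor_module")
  a_maf <- runif(2, 0.2, 0.4)
  a_dos <- cbind(rbinom(n, 2L, a_maf[1]), rbinom(n, 2L, a_maf[2]))
  colnames(a_dos) <- anchors
  dosage <- cbind(dosage, a_dos)
  info <- tibble::tibble(
    snp_id = c(snp_id, anchors),
    chromosome = as.character(c(snp_chrom, 1L, 2L)),
    position = c(snp_pos, round(config$chrom_length * c(0.31, 0.87))),
    maf = c(maf, a_maf))

  ## ---- causal topology between trait core and module-1 factor ------------
  a <- sqrt(config$anchor_r2)
  b <- config$topology_path
  m_t <- .std(dosage[, "anchor_trait"])
  m_f <- .std(dosage[, "anchor_module"])
  e_node <- sqrt(1 - a^2 - b^2)
  trait_core <- NULL
  f1 <- NULL
  switch(config$causal_topology,
    causal = {
      trait_core <- a * m_t + sqrt(1 - a^2) * rnorm(n)
      f1 <- b * trait_core + a * m_f + e_node * rnorm(n)
    },
    reactive = {
      f1 <- a * m_f + sqrt(1 - a^2) * rnorm(n)
      trait_core <- b * f1 + a * m_t + e_node * rnorm(n)
    },
    confounded = {
      conf <- rnorm(n)
      trait_core <- a * m_t + b * conf + e_node * rnorm(n)
      f1 <- a * m_f + b * conf + e_node * rnorm(n)
    },
    independent = {
      trait_core <- a * m_t + sqrt(1 - a^2) * rnorm(n)
      f1 <- a * m_f + sqrt(1 - a^2) * rnorm(n)
    })

  ## ---- latent factors and expression -------------------------------------
  factors <- matrix(rnorm(max(config$n_modules, 0) * n,
                          sd = config$module_factor_sd),
                    nrow = max(config$n_modules, 0))
  if (config$n_modules > 0) factors[1, ] <- f1 * config$module_factor_sd
  baseline <- runif(p, 6, 12)
  expr <- baseline +
    matrix(rnorm(p * n, sd = config$noise_sd), nrow = p)
  in_mod <- assignment > 0
  if (any(in_mod))
    expr[in_mod, ] <- expr[in_mod, ] +
      loadings[in_mod] * factors[assignment[in_mod], , drop = FALSE]
  eqtl_map <- tibble::tibble(snp_id = character(), probe_id = character(),
                             effect = numeric())
  if (n_cis > 0) {
    effect <- config$cis_effect * config$noise_sd
    for (i in seq_len(n_cis))
      expr[cis_targets[i], ] <- expr[cis_targets[i], ] + effect * dosage[, i]
    eqtl_map <- tibble::tibble(snp_id = snp_id[seq_len(n_cis)],
                               probe_id = probe_id[cis_targets],
                               effect = effect)
  }
  dimnames(expr) <- list(probe_id, rownames(dosage))

  ## ---- technical replicates (linear scale) with bead counts --------------
  corrupted <- runif(n) < config$corrupt_fraction
  tech1 <- matrix(rnorm(p * n, sd = config$replicate_tech_sd), nrow = p)
  tech2 <- matrix(rnorm(p * n, sd = config$replicate_tech_sd), nrow = p)
  tech2[, corrupted] <- tech2[, corrupted] * 10
  reps <- list(
    S1 = 2^(expr + tech1), S2 = 2^(expr + tech2),
    b1 = matrix(sample(10:60, p * n, replace = TRUE), nrow = p),
    b2 = matrix(sample(10:60, p * n, replace = TRUE), nrow = p),
    corrupted = setNames(corrupted, colnames(expr)))
  for (l in c("S1", "S2", "b1", "b2")) dimnames(reps[[l]]) <- dimnames(expr)

  ## ---- traits and covariates ---------------------------------------------
  male <- runif(n) < config$male_fraction
  age <- round(runif(n, 25, 74))
  f_std <- if (config$n_modules > 0)
    factors / config$module_factor_sd else factors
  specs <- config$trait_specs
  tl <- config$trait_loadings
  trait_vals <- matrix(NA_real_, n, nrow(specs),
                       dimnames = list(NULL, specs$name))
  for (j in seq_len(nrow(specs))) {
    nm <- specs$name[j]
    if (nm == config$topology_trait &&
        config$causal_topology != "independent" && config$n_modules > 0) {
      z <- trait_core
      tl[nm, ] <- 0; tl[nm, 1] <- b
    } else {
      lj <- if (config$n_modules > 0) tl[j, ] else numeric(0)
      sys <- if (length(lj)) drop(lj %*% f_std) else 0
      z <- sys + sqrt(max(0, 1 - sum(lj^2))) * rnorm(n)
    }
    if (config$confound_age)
      z <- sqrt(1 - 0.04) * z + 0.2 * .std(age)
    trait_vals[, j] <- ifelse(male,
      specs$male_mean[j] + specs$male_sd[j] * z,
      specs$female_mean[j] + specs$female_sd[j] * z)
  }
  traits <- tibble::tibble(
    sample_id = colnames(expr),
    sex = ifelse(male, "male", "female"),
    age = age,
    HTM = runif(n) < config$htm_prevalence,
    CM = runif(n) < config$cm_prevalence,
    alcohol = round(exp(rnorm(n, 3.1, 0.9))))
  traits <- dplyr::bind_cols(traits, tibble::as_tibble(trait_vals))
  attr(traits, "trait_names") <- specs$name

  truth <- structure(list(
    module_assignment = setNames(assignment, probe_id),
    latent_factors = factors,
    loadings = setNames(loadings, probe_id),
    eqtl_map = eqtl_map,
    anchor_map = tibble::tibble(
      snp_id = anchors,
      node = c(paste0("trait:", config$topology_trait), "module:1"),
      topology = config$causal_topology),
    trait_loadings = tl), class = "ground_truth")

  structure(list(
    expression = structure(list(log2 = expr, annotation = annotation,
                                replicates = reps),
                           class = "expression_dataset"),
    genotypes = structure(list(dosage = dosage, info = info),
                          class = "genotype_dataset"),
    traits = traits,
    truth = truth,
    config = config), class = "sim_dataset")
}

#' Generate expression data (with ground truth)
#'
#' Deterministic view of [simulate_dataset()]: returns the expression layer
#' (planted modules, replicate pairs, annotation flags) together with the
#' ground-truth record. Because the full simulation is a pure function of the
#' configuration, the expression, genotype and trait views drawn from the
#' same config are mutually consistent.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expression` and `truth`.
#' @export
generate_expression <- function(config = sim_config()) {
  ds <- simulate_dataset(config)
  list(expression = ds$expression, truth = ds$truth)
}

#' Generate genotype data consistent with a ground truth
#'
#' @param config A [sim_config()] object.
#' @param truth Optional `ground_truth` from [generate_expression()]; must
#'   come from the same configuration.
#' @return A `genotype_dataset` (samples x SNPs dosage matrix in
#'   Hardy-Weinberg equilibrium at the configured MAFs, plus SNP positions).
#' @export
generate_genotypes <- function(config = sim_config(), truth = NULL) {
  ds <- simulate_dataset(config)
  if (!is.null(truth) &&
      !identical(truth$module_assignment, ds$truth$module_assignment))
    stop("`truth` was generated from a different configuration", call. = FALSE)
  ds$genotypes
}

#' Generate the trait table consistent with a ground truth
#'
#' @inheritParams generate_genotypes
#' @return A tibble of per-sample traits (clinical scales) and covariates
#'   (`sex`, `age`, `HTM`, `CM`, `alcohol`).
#' @export
generate_traits <- function(config = sim_config(), truth = NULL) {
  ds <- simulate_dataset(config)
  if (!is.null(truth) &&
      !identical(truth$module_assignment, ds$truth$module_assignment))
    stop("`truth` was generated from a different configuration", call. = FALSE)
  ds$traits
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$expression$log2), " probes x ",
      ncol(x$expression$log2), " samples, ",
      ncol(x$genotypes$dosage), " SNPs, ",
      length(attr(x$traits, "trait_names")), " traits; topology: ",
      x$config$causal_topology, "\n", sep = "")
  invisible(x)
}
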