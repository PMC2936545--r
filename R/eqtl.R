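# cis/trans window classification relative to a probe midpoint.
# cis: same chromosome and distance <= cis_window (1 Mb).
# trans: different chromosome or distance > trans_gap (5 Mb).
# The 1-5 Mb band on the same chromosome belongs to neither scan.
.snp_zone <- function(info, probe_chrom, probe_pos,
                      cis_window = 1e6, trans_gap = 5e6) {
  same <- info$chromosome == as.character(probe_chrom)
  dist <- abs(info$position - probe_pos)
  dplyr::case_when(
    same & dist <= cis_window ~ "cis",
    !same | dist > trans_gap ~ "trans",
    .default = "excluded")
}

#' cis-eQTL scan for one probe
#'
#' For every SNP within `cis_window` (default 1 Mb) of the probe midpoint, a
#' simple linear regression of log2 expression on minor-allele dosage (0, 1,
#' 2) is fitted; missing genotypes are dropped pairwise and monomorphic
#' SNPs are skipped.
#'
#' @param expr Per-sample log2 expression vector for the probe.
#' @param genotypes A `genotype_dataset`.
#' @param probe_chrom,probe_pos Probe midpoint location (1-based).
#' @param cis_window Window half-width in bp.
#' @param min_n Minimum complete pairs per SNP (default 10).
#' @return Tibble: `snp_id`, `position`, `slope`, `se`, `statistic`,
#'   `p_value`, `n`, `skipped` reason (`""` when tested).
#' @export
cis_scan <- function(expr, genotypes, probe_chrom, probe_pos,
                     cis_window = 1e6, min_n = 10) {
  info <- genotypes$info
  zone <- .snp_zone(info, probe_chrom, probe_pos, cis_window)
  idx <- which(zone == "cis")
  if (!length(idx))
    return(tibble::tibble(snp_id = character(), position = numeric(),
                          slope = numeric(), se = numeric(),
                          statistic = numeric(), p_value = numeric(),
                          n = integer(), skipped = character()))
  purrr::map_dfr(idx, function(j) {
    g <- genotypes$dosage[, info$snp_id[j]]
    ok <- complete.cases(expr, g)
    base <- tibble::tibble(snp_id = info$snp_id[j],
                           position = info$position[j], slope = NA_real_,
                           se = NA_real_, statistic = NA_real_,
                           p_value = NA_real_, n = sum(ok), skipped = "")
    if (sum(ok) < min_n) { base$skipped <- "too_few"; return(base) }
    g <- g[ok]; y <- expr[ok]
    if (var(g) == 0) { base$skipped <- "monomorphic"; return(base) }
    fit <- lm(y ~ g)
    sm <- summary(fit)$coefficients
    base$slope <- sm["g", 1]; base$se <- sm["g", 2]
    base$statistic <- sm["g", 3]; base$p_value <- sm["g", 4]
    base
  })
}

#' Permutation calibration of a probe's cis scan
#'
#' Generates the null distribution of the probe's best cis association by
#' permuting expression relative to genotypes: in each permutation the
#' minimum nominal P value across the probe's cis SNPs is recorded, and the
#' empirical P value is `(1 + #{permutation min-P <= observed min-P}) /
#' (n_perm + 1)`. The probe passes at `alpha` (default 0.05).
#'
#' @param expr Per-sample expression vector.
#' @param genotypes A `genotype_dataset`.
#' @param probe_chrom,probe_pos Probe midpoint.
#' @param n_perm Number of permutations (default 10000; fewer than 100
#'   triggers a resolution warning).
#' @param alpha Permutation threshold.
#' @param seed Integer seed for the permutation stream.
#' @param cis_window Window half-width in bp.
#' @return List with `empirical_p`, `observed_min_p`, `n_perm`, `pass`, and
#'   the observed `scan` tibble.
#' @export
permutation_calibrate <- function(expr, genotypes, probe_chrom, probe_pos,
                                  n_perm = 10000, alpha = 0.05, seed = 1L,
                                  cis_window = 1e6) {
  if (n_perm < 100)
    warning("fewer than 100 permutations gives poor resolution",
            call. = FALSE)
  scan <- cis_scan(expr, genotypes, probe_chrom, probe_pos, cis_window)
  tested <- scan[scan$skipped == "", , drop = FALSE]
  if (nrow(tested) == 0)
    return(list(empirical_p = NA_real_, observed_min_p = NA_real_,
                n_perm = n_perm, pass = FALSE, scan = scan))
  obs <- min(tested$p_value)
  G <- genotypes$dosage[, tested$snp_id, drop = FALSE]
  keep <- complete.cases(G, expr)
  G <- G[keep, , drop = FALSE]
  y <- expr[keep]
  n <- length(y)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  # correlation-based minimum P across cis SNPs, vectorized over permutations
  Yp <- matrix(y[perm_idx], nrow = n)
  R <- suppressWarnings(cor(Yp, G))
  R[is.na(R)] <- 0
  R2 <- pmin(R^2, 1 - 1e-15)
  tstat <- sqrt(R2 * (n - 2) / (1 - R2))
  minp <- apply(2 * pt(-tstat, n - 2), 1, min)
  emp <- (1 + sum(minp <= obs)) / (n_perm + 1)
  list(empirical_p = emp, observed_min_p = obs, n_perm = n_perm,
       pass = emp < alpha, scan = scan)
}

#' trans-eQTL scan for one probe
#'
#' Tests every SNP more than 5 Mb from the probe midpoint or on a different
#' chromosome with the Spearman rank correlation (genotype ranks over 0/1/2
#' with midranks) and its n - 2 df t-test; SNPs with nominal P below
#' `threshold` (default 5.0e-7) are flagged significant.
#'
#' @param expr Per-sample expression vector (constant expression yields an
#'   empty result with a message).
#' @param genotypes A `genotype_dataset`.
#' @param probe_chrom,probe_pos Probe midpoint.
#' @param threshold Significance threshold on the nominal Spearman P.
#' @param trans_gap Minimum same-chromosome distance in bp.
#' @return Tibble: `snp_id`, `position`, `chromosome`, `rho`, `p_value`,
#'   `significant`.
#' @export
trans_scan <- function(expr, genotypes, probe_chrom, probe_pos,
                       threshold = 5e-7, trans_gap = 5e6) {
  if (sd(expr, na.rm = TRUE) == 0) {
    message("trans_scan: constant expression, no tests performed")
    return(tibble::tibble(snp_id = character(), position = numeric(),
                          chromosome = character(), rho = numeric(),
                          p_value = numeric(), significant = logical()))
  }
  info <- genotypes$info
  zone <- .snp_zone(info, probe_chrom, probe_pos, trans_gap = trans_gap)
  idx <- which(zone == "trans")
  if (!length(idx))
    return(tibble::tibble(snp_id = character(), position = numeric(),
                          chromosome = character(), rho = numeric(),
                          p_value = numeric(), significant = logical()))
  purrr::map_dfr(idx, function(j) {
    g <- genotypes$dosage[, info$snp_id[j]]
    ok <- complete.cases(expr, g)
    if (sum(ok) < 3 || var(g[ok]) == 0)
      return(tibble::tibble(snp_id = info$snp_id[j],
                            position = info$position[j],
                            chromosome = info$chromosome[j], rho = NA_real_,
                            p_value = NA_real_, significant = FALSE))
    st <- spearman_test(expr[ok], g[ok])
    tibble::tibble(snp_id = info$snp_id[j], position = info$position[j],
                   chromosome = info$chromosome[j], rho = st$rho,
                   p_value = st$p_value,
                   significant = !is.na(st$p_value) & st$p_value < threshold)
  })
}

#' Module-level eQTL test (multivariate)
#'
#' Regresses the module's probe expression matrix jointly on a SNP's
#' minor-allele dosage and tests the SNP term with Wilks' lambda (shared
#' with [fit_meta_lipids()]); with a single-probe module this reduces to the
#' univariate regression P value.
#'
#' @param expr_module Probes x samples expression matrix for the module.
#' @param snp Per-sample dosage vector.
#' @param covariates Optional covariate tibble.
#' @return An `ll_wilks` object.
#' @export
module_eqtl <- function(expr_module, snp, covariates = NULL) {
  Y <- t(as.matrix(expr_module))
  ok <- complete.cases(Y, snp)
  fit_meta_lipids(Y[ok, , drop = FALSE], snp[ok],
                  covariates = if (!is.null(covariates))
                    covariates[ok, , drop = FALSE])
}
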