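#' Quantile normalization
#'
#' Forces every column (sample) of a matrix to share the same distribution:
#' the cross-column mean quantile vector. Tied values within a column receive
#' the mean of the pooled quantiles they span (midrank interpolation), so the
#' operation is idempotent. With `groups`, normalization is applied within
#' each group of columns separately (e.g. per array strip).
#'
#' @param x Numeric matrix (e.g. probes x samples), no missing values.
#' @param groups Optional factor of length `ncol(x)` defining normalization
#'   groups.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x, groups = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != ncol(x))
      stop("`groups` must have one entry per column", call. = FALSE)
    for (g in levels(groups)) {
      idx <- which(groups == g)
      x[, idx] <- quantile_normalize(x[, idx, drop = FALSE])
    }
    return(x)
  }
  if (ncol(x) == 1) return(x)
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(xj) {
    o <- order(xj)
    grp <- cumsum(!duplicated(xj[o]))  # tie groups occupy consecutive ranks
    res <- ave(target, grp, FUN = mean)
    xj[o] <- res
    xj
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Technical replicate quality control
#'
#' Each sample was hybridized in duplicate; after log2 transformation and
#' quantile normalization of all replicate arrays together, the two
#' replicates of a sample are compared by Pearson's product-moment
#' correlation and Spearman's rank correlation. A sample is dropped when its
#' Pearson correlation falls below `pearson_min` (default 0.94) or its
#' Spearman correlation below `spearman_min` (default 0.60). Degenerate
#' (zero-variance) replicates are dropped with reason `"degenerate"`.
#'
#' @param replicates List with linear-scale signal matrices `S1`, `S2`
#'   (probes x samples) as produced by [simulate_dataset()], or any pair of
#'   identically indexed matrices.
#' @param pearson_min,spearman_min Drop thresholds.
#' @return A tibble (class `ll_qc_replicates`) with one row per sample:
#'   `sample_id`, `pearson`, `spearman`, `kept`, `reason`.
#' @export
qc_replicates <- function(replicates, pearson_min = 0.94,
                          spearman_min = 0.60) {
  S1 <- as.matrix(replicates$S1); S2 <- as.matrix(replicates$S2)
  stopifnot(identical(dim(S1), dim(S2)), nrow(S1) >= 2)
  ids <- colnames(S1)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(ncol(S1)))
  norm <- quantile_normalize(log2(cbind(S1, S2)))
  L1 <- norm[, seq_len(ncol(S1)), drop = FALSE]
  L2 <- norm[, ncol(S1) + seq_len(ncol(S2)), drop = FALSE]
  res <- purrr::map_dfr(seq_along(ids), function(i) {
    x <- L1[, i]; y <- L2[, i]
    if (sd(x) == 0 || sd(y) == 0)
      return(tibble::tibble(sample_id = ids[i], pearson = NA_real_,
                            spearman = NA_real_, kept = FALSE,
                            reason = "degenerate"))
    pe <- cor(x, y); sp <- cor(x, y, method = "spearman")
    kept <- pe >= pearson_min && sp >= spearman_min
    tibble::tibble(sample_id = ids[i], pearson = pe, spearman = sp,
                   kept = kept,
                   reason = ifelse(kept, "", ifelse(pe < pearson_min,
                                                    "pearson", "spearman")))
  })
  class(res) <- c("ll_qc_replicates", class(res))
  res
}

#' MA coordinates between a sample's replicates
#'
#' M = log2(S1) - log2(S2), A = (log2(S1) + log2(S2)) / 2, computed per
#' probe; used to inspect replicate agreement for intensity-dependent bias.
#'
#' @param s1,s2 Linear-scale signal vectors for one sample.
#' @return A tibble with columns `A` and `M`.
#' @export
replicate_ma <- function(s1, s2) {
  l1 <- log2(s1); l2 <- log2(s2)
  tibble::tibble(A = (l1 + l2) / 2, M = l1 - l2)
}

#' Combine technical replicates by bead-weighted averaging
#'
#' Each probe's two replicate signals are weighted by the number of beads
#' contributing to each signal and combined into a single intensity
#' \eqn{\delta_p = (b_{1p} S_{1p} + b_{2p} S_{2p}) / (b_{1p} + b_{2p})}.
#' With equal bead counts this is the arithmetic mean, and the result always
#' lies between the two replicate signals.
#'
#' @param s1,s2 Signal vectors or matrices (linear scale).
#' @param b1,b2 Bead counts (positive integers), same shape.
#' @return Combined signal, same shape as the inputs.
#' @export
combine_replicates <- function(s1, s2, b1, b2) {
  if (any(b1 <= 0) || any(b2 <= 0))
    stop("bead counts must be positive", call. = FALSE)
  (b1 * s1 + b2 * s2) / (b1 + b2)
}

#' Probe filtering on annotation
#'
#' A probe is kept if and only if it is autosomal, not complementary to cDNA
#' from erythrocyte globin components, and maps to exactly one genomic
#' position.
#'
#' @param annotation Tibble with columns `chromosome` (autosomes as numbers
#'   or `"1"`-style strings), `globin` (logical) and `n_mappings` (integer).
#' @return Logical keep mask, one entry per probe.
#' @export
filter_probes <- function(annotation) {
  autosomal <- !is.na(suppressWarnings(as.integer(annotation$chromosome)))
  autosomal & !annotation$globin & annotation$n_mappings == 1L
}

.boxcox_loglik <- function(lambda, y) {
  # profile log-likelihood of the power transform at fixed lambda
  n <- length(y)
  z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  -n / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * sum(log(y))
}

#' Box-Cox power transformation by profile maximum likelihood
#'
#' @param y Positive numeric vector.
#' @param interval Search interval for lambda.
#' @return Transformed vector with attributes `lambda` (ML estimate).
#' @export
boxcox_transform <- function(y, interval = c(-5, 5)) {
  if (any(y <= 0))
    stop("Box-Cox requires positive values; shift or exclude nonpositive ",
         "measurements first", call. = FALSE)
  opt <- optimise(.boxcox_loglik, interval, y = y, maximum = TRUE)
  lambda <- opt$maximum
  z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  attr(z, "lambda") <- lambda
  z
}

#' Gender-stratified trait standardization
#'
#' Trait distributions for males and females are treated separately. Within
#' each sex, normality is assessed with an Anderson-Darling test; if P <
#' `ad_alpha` (default 0.01) a Box-Cox power transformation (lambda by
#' profile maximum likelihood) is applied first. The (possibly transformed)
#' values are then standardized to Z-scores (mean 0, sd 1) within sex, and
#' the two sexes are recombined in the original sample order.
#'
#' @param values Numeric trait vector.
#' @param sex Character/factor vector (two levels, e.g. "male"/"female");
#'   a single level is allowed and processed as one stratum.
#' @param ad_alpha Anderson-Darling significance gate for transformation.
#' @return Z-score vector with attribute `meta`: a tibble per stratum with
#'   the Anderson-Darling P value and the Box-Cox lambda (NA when no
#'   transformation was applied).
#' @export
transform_trait <- function(values, sex, ad_alpha = 0.01) {
  stopifnot(length(values) == length(sex))
  out <- rep(NA_real_, length(values))
  meta <- list()
  for (s in unique(as.character(sex))) {
    idx <- which(sex == s)
    y <- values[idx]
    if (length(unique(y)) < 2)
      stop("trait is constant within stratum '", s, "'", call. = FALSE)
    ad_p <- nortest::ad.test(y)$p.value
    lambda <- NA_real_
    if (ad_p < ad_alpha) {
      y <- boxcox_transform(y)
      lambda <- attr(y, "lambda")
    }
    out[idx] <- (y - mean(y)) / sd(y)
    meta[[s]] <- tibble::tibble(stratum = s, ad_p = ad_p, lambda = lambda)
  }
  attr(out, "meta") <- dplyr::bind_rows(meta)
  out
}

#' Standardize all traits in a trait table
#'
#' Applies [transform_trait()] to each trait column, adding `z_<trait>`
#' columns.
#'
#' @param traits Trait tibble with a `sex` column and an attached
#'   `trait_names` attribute (or give `trait_names` explicitly).
#' @param trait_names Character vector of trait columns.
#' @return The tibble with Z-score columns appended.
#' @export
standardize_traits <- function(traits,
                               trait_names = attr(traits, "trait_names")) {
  if (is.null(trait_names))
    stop("`trait_names` must be supplied", call. = FALSE)
  for (nm in trait_names)
    traits[[paste0("z_", nm)]] <-
      as.numeric(transform_trait(traits[[nm]], traits$sex))
  attr(traits, "trait_names") <- trait_names
  traits
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions for a biallelic SNP:
#' the P value is the total probability, under the conditional distribution
#' of the heterozygote count given allele counts, of all genotype
#' configurations no more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote; order does not matter).
#' @return Exact P value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)  # heterozygote counts sharing parity
  # log P(n_ab = h | allele counts) up to a common constant
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (2 * n - rare - h) / 2
    h * log(2) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[match(n_ab, hets)] * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Applies the sample and SNP gates in order: samples with call rate below
#' `sample_call_rate` are removed; then a SNP is kept if and only if its
#' call rate exceeds `call_rate` (default 0.95), its minor allele frequency
#' exceeds `maf_min` (default 0.01) and its Hardy-Weinberg exact P value
#' exceeds `hwe_min` (default 1e-6). An externally supplied exclusion list
#' (fingerprint or relatedness failures determined upstream) is honoured
#' first.
#'
#' @param genotypes A `genotype_dataset` (list with samples x SNPs `dosage`
#'   matrix and `info` tibble).
#' @param call_rate,maf_min,hwe_min SNP gates.
#' @param sample_call_rate Sample gate.
#' @param exclude_samples Character vector of sample ids to drop up front.
#' @return List with the filtered `genotypes`, a per-SNP `snp_report` tibble
#'   (`snp_id`, `call_rate`, `maf`, `hwe_p`, `kept`, `reason`) and a
#'   `sample_report` tibble.
#' @export
qc_genotypes <- function(genotypes, call_rate = 0.95, maf_min = 0.01,
                         hwe_min = 1e-6, sample_call_rate = 0.95,
                         exclude_samples = character()) {
  G <- genotypes$dosage
  ids <- rownames(G)
  keep_s <- !(ids %in% exclude_samples)
  s_cr <- rowMeans(!is.na(G))
  reason_s <- ifelse(!keep_s, "excluded",
                     ifelse(s_cr < sample_call_rate, "call_rate", ""))
  keep_s <- keep_s & s_cr >= sample_call_rate
  sample_report <- tibble::tibble(sample_id = ids, call_rate = s_cr,
                                  kept = keep_s, reason = reason_s)
  G <- G[keep_s, , drop = FALSE]

  cr <- colMeans(!is.na(G))
  stats <- purrr::map_dfr(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    counts <- tabulate(g + 1L, nbins = 3L)
    maf <- if (length(g)) min(mean(g) / 2, 1 - mean(g) / 2) else NA_real_
    tibble::tibble(maf = maf,
                   hwe_p = hwe_exact_p(counts[1], counts[2], counts[3]))
  })
  kept <- cr > call_rate & stats$maf > maf_min &
    (is.na(stats$hwe_p) | stats$hwe_p > hwe_min)
  kept[is.na(kept)] <- FALSE
  reason <- dplyr::case_when(
    cr <= call_rate ~ "call_rate",
    stats$maf <= maf_min ~ "maf",
    !is.na(stats$hwe_p) & stats$hwe_p <= hwe_min ~ "hwe",
    .default = "")
  snp_report <- tibble::tibble(snp_id = colnames(G), call_rate = cr,
                               maf = stats$maf, hwe_p = stats$hwe_p,
                               kept = kept, reason = reason)
  filtered <- structure(list(
    dosage = G[, kept, drop = FALSE],
    info = genotypes$info[match(colnames(G)[kept], genotypes$info$snp_id), ]),
    class = "genotype_dataset")
  list(genotypes = filtered, snp_report = snp_report,
       sample_report = sample_report)
}

#' Tracy-Widom (order 1) upper-tail probability
#'
#' Computed from the shifted-gamma approximation to the Tracy-Widom law of
#' order 1 (shape 46.446, scale 0.18605, shift 9.84801), accurate to about
#' 1e-3 in CDF over the relevant range.
#'
#' @param x Tracy-Widom statistic(s).
#' @return Upper-tail probability.
#' @export
tracy_widom_p <- function(x) {
  stats::pgamma(x + 9.848007781, shape = 46.44604884,
                scale = 0.186054, lower.tail = FALSE)
}

# Patterson-style eigenvalue standardization: returns the TW statistic of the
# leading eigenvalue among `ev`, using the moment estimator of the effective
# number of markers.
.tw_stat <- function(ev, m) {
  ev <- ev[ev > 1e-12]
  p <- length(ev)
  if (p < 2) return(-Inf)
  n_eff <- ((m + 1) * sum(ev)^2) / ((m - 1) * sum(ev^2) - sum(ev)^2)
  l1 <- p * ev[1] / sum(ev)
  mu <- (sqrt(n_eff - 1) + sqrt(p))^2 / n_eff
  sig <- (sqrt(n_eff - 1) + sqrt(p)) / n_eff *
    (1 / sqrt(n_eff - 1) + 1 / sqrt(p))^(1 / 3)
  (l1 - mu) / sig
}

#' Genotype PCA outlier detection
#'
#' Finds population-structure outliers: each SNP dosage is residualized on
#' the two preceding SNPs of the same chromosome (to damp linkage
#' disequilibrium), standardized, and the samples are decomposed by PCA.
#' Principal components are deemed significant while their Tracy-Widom P
#' value is below `tw_alpha` (default 0.01), and a sample is flagged when its
#' score on any significant component exceeds `sd_threshold` (default 8)
#' standard deviations. A single pass is performed.
#'
#' @param genotypes A `genotype_dataset` (filtered; missing dosages are mean
#'   imputed for the decomposition).
#' @param sd_threshold Outlier gate in component standard deviations.
#' @param tw_alpha Tracy-Widom significance gate per component.
#' @param max_components Number of leading components assessed.
#' @return List with `outliers` (sample ids), `scores` (samples x assessed
#'   components), and `components` tibble (`component`, `eigenvalue`,
#'   `tw_stat`, `tw_p`, `significant`).
#' @export
pca_outliers <- function(genotypes, sd_threshold = 8, tw_alpha = 0.01,
                         max_components = 10) {
  G <- genotypes$dosage
  if (nrow(G) < 10) stop("need at least 10 samples", call. = FALSE)
  info <- genotypes$info[match(colnames(G), genotypes$info$snp_id), ]
  ord <- order(info$chromosome, info$position)
  G <- G[, ord, drop = FALSE]
  chrom <- info$chromosome[ord]

  X <- matrix(0, nrow(G), ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    prev <- which(chrom == chrom[j] & seq_len(ncol(G)) < j)
    prev <- utils::tail(prev, 2)
    r <- if (length(prev)) {
      P <- G[, prev, drop = FALSE]
      P[is.na(P)] <- 0
      resid(lm(g ~ P))
    } else g
    s <- sd(r)
    X[, j] <- if (s > 0) (r - mean(r)) / s else 0
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(max_components, length(ev) - 1)
  tw <- vapply(seq_len(k), function(i) .tw_stat(ev[i:length(ev)], ncol(X)),
               numeric(1))
  twp <- tracy_widom_p(tw)
  sig <- cumprod(twp < tw_alpha) > 0  # leading run of significant components
  comp <- tibble::tibble(component = seq_len(k), eigenvalue = ev[seq_len(k)],
                         tw_stat = tw, tw_p = twp, significant = sig)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(G)
  out <- character()
  if (any(sig)) {
    z <- scale(scores[, sig, drop = FALSE])
    out <- rownames(G)[apply(abs(z) > sd_threshold, 1, any)]
  }
  list(outliers = out, scores = scores, components = comp)
}
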