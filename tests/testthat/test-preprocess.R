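test_that("quantile normalization equalizes column distributions", {
  set.seed(1)
  x <- matrix(rnorm(200, sd = c(1, 2, 5, 0.5)), 50, 4, byrow = TRUE)
  q <- quantile_normalize(x)
  # every column carries the same sorted multiset
  sorted <- apply(q, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2], tolerance = 1e-12)
  expect_equal(sorted[, 1], sorted[, 4], tolerance = 1e-12)
  expect_equal(var(colMeans(q)), 0, tolerance = 1e-24)
  # permuted columns normalize to the same values up to the permutation
  p <- sample(50)
  x2 <- cbind(x[, 1], x[p, 1])
  q2 <- quantile_normalize(x2)
  expect_equal(q2[, 2], q2[p, 1], tolerance = 1e-12)
})

test_that("quantile normalization is idempotent and matches limma", {
  set.seed(2)
  x <- matrix(rexp(60), 20, 3)
  q <- quantile_normalize(x)
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)
  skip_if_not_installed("limma")
  expect_equal(unname(q), unname(limma::normalizeQuantiles(x)),
               tolerance = 1e-10)
  # grouped normalization treats groups independently
  g <- quantile_normalize(cbind(x, 10 * x), groups = rep(1:2, each = 3))
  expect_equal(g[, 1:3], q, tolerance = 1e-12)
})

test_that("replicate QC applies the Pearson/Spearman gates", {
  set.seed(3)
  base <- matrix(2^rnorm(300, 8), 100, 3,
                 dimnames = list(NULL, c("good", "bad", "flat")))
  reps <- list(S1 = base, S2 = base)
  # "bad": anti-correlated second replicate; "flat": constant
  reps$S2[, "bad"] <- 2^(16 - log2(base[, "bad"]))
  reps$S1[, "flat"] <- 2^8
  qc <- qc_replicates(reps)
  expect_true(qc$kept[qc$sample_id == "good"])
  expect_equal(qc$pearson[qc$sample_id == "good"], 1, tolerance = 1e-9)
  expect_false(qc$kept[qc$sample_id == "bad"])
  expect_lt(qc$pearson[qc$sample_id == "bad"], 0)
  expect_equal(qc$reason[qc$sample_id == "flat"], "degenerate")
})

test_that("corrupted replicates are dropped at close to the injected rate", {
  cfg <- sim_config(n_samples = 400, n_probes = 200, n_modules = 1,
                    module_sizes = 20, n_snps = 10, n_cis_eqtl = 0,
                    corrupt_fraction = 0.10, seed = 99)
  ds <- simulate_dataset(cfg)
  qc <- qc_replicates(ds$expression$replicates)
  dropped <- !qc$kept
  corrupted <- ds$expression$replicates$corrupted
  # all drops are corrupted samples, and most corrupted samples drop
  expect_true(all(corrupted[dropped]))
  expect_gt(sum(dropped), 0.5 * sum(corrupted))
})

test_that("bead-weighted combination is a convex weighted mean", {
  expect_equal(combine_replicates(10, 20, 1, 1), 15)
  expect_equal(combine_replicates(10, 20, 3, 1), 12.5)
  expect_error(combine_replicates(10, 20, 0, 1), "positive")
  set.seed(4)
  s1 <- runif(50); s2 <- runif(50)
  b1 <- sample(1:60, 50, TRUE); b2 <- sample(1:60, 50, TRUE)
  d <- combine_replicates(s1, s2, b1, b2)
  expect_true(all(d >= pmin(s1, s2) - 1e-12 & d <= pmax(s1, s2) + 1e-12))
  expect_equal(combine_replicates(s1, s2, rep(5, 50), rep(5, 50)),
               (s1 + s2) / 2)
})

test_that("probe filter keeps autosomal unique non-globin probes only", {
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:5),
    chromosome = c("1", "X", "2", "2", "1"),
    globin = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    n_mappings = c(1L, 1L, 1L, 2L, 1L))
  expect_equal(filter_probes(ann), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # exact kept count on a synthetic panel with 10% flagged
  ds <- simulate_dataset(small_config(flagged_fraction = 0.10))
  keep <- filter_probes(ds$expression$annotation)
  flagged <- with(ds$expression$annotation,
                  chromosome == "X" | globin | n_mappings > 1)
  expect_equal(sum(keep), nrow(ds$expression$annotation) - sum(flagged))
})

test_that("trait standardization is per-sex with Box-Cox when non-normal", {
  set.seed(5)
  sex <- rep(c("male", "female"), each = 250)
  normal <- rnorm(500, 10, 2)
  z <- transform_trait(normal, sex)
  meta <- attr(z, "meta")
  expect_true(all(is.na(meta$lambda)))  # no transformation triggered
  for (s in c("male", "female")) {
    expect_equal(mean(z[sex == s]), 0, tolerance = 1e-12)
    expect_equal(sd(z[sex == s]), 1, tolerance = 1e-12)
  }
  # lognormal branch: lambda near the log limit
  ln <- exp(rnorm(500, 1, 0.8))
  zl <- transform_trait(ln, rep("all", 500))
  lam <- attr(zl, "meta")$lambda
  expect_false(is.na(lam))
  expect_lt(abs(lam), 0.2)
  expect_error(transform_trait(rep(3, 20), rep("m", 20)), "constant")
})

test_that("Box-Cox profile likelihood matches the MASS grid oracle", {
  skip_if_not_installed("MASS")
  set.seed(6)
  y <- rgamma(300, shape = 2, rate = 0.5)
  lam <- attr(boxcox_transform(y), "lambda")
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 1e-3), plotit = FALSE)
  expect_lt(abs(lam - bc$x[which.max(bc$y)]), 2e-3)
})

test_that("transformed lognormal traits pass the normality gate", {
  set.seed(7)
  pass <- vapply(1:20, function(i) {
    y <- exp(rnorm(500))
    z <- transform_trait(y, rep("s", 500))
    nortest::ad.test(as.numeric(z))$p.value >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("HWE exact test matches a brute-force enumeration oracle", {
  # oracle: direct conditional probabilities from factorials
  oracle <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    na <- 2 * naa + nab
    hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), 2)
    pr <- vapply(hets, function(h) {
      haa <- (na - h) / 2; hbb <- n - haa - h
      exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
            h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
            lfactorial(2 * n))
    }, numeric(1))
    sum(pr[pr <= pr[match(nab, hets)] * (1 + 1e-12)])
  }
  expect_equal(hwe_exact_p(25, 50, 25), 1)
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    g <- tabulate(sample(0:2, n, TRUE, prob = c(0.4, 0.4, 0.2)) + 1L, 3)
    expect_equal(hwe_exact_p(g[1], g[2], g[3]), oracle(g[1], g[2], g[3]),
                 tolerance = 1e-12)
  }
})

test_that("genotype QC applies call-rate, MAF and HWE gates", {
  set.seed(9)
  n <- 200
  filler <- vapply(1:40, function(i) rbinom(n, 2, 0.3), numeric(n))
  colnames(filler) <- sprintf("fill%02d", 1:40)
  G <- cbind(
    ok = rbinom(n, 2, 0.3),
    missing10 = replace(rbinom(n, 2, 0.3), sample(n, 20), NA),
    rare = rbinom(n, 2, 0.004),
    hwe_bad = sample(c(0, 2), n, TRUE),  # no heterozygotes at MAF ~0.5
    filler)
  rownames(G) <- sprintf("s%03d", seq_len(n))
  gd <- structure(list(dosage = G, info = tibble::tibble(
    snp_id = colnames(G), chromosome = "1",
    position = seq_len(ncol(G)) * 100)), class = "genotype_dataset")
  qc <- qc_genotypes(gd)
  rep_ <- qc$snp_report
  expect_true(rep_$kept[rep_$snp_id == "ok"])
  expect_equal(rep_$reason[rep_$snp_id == "missing10"], "call_rate")
  expect_equal(rep_$reason[rep_$snp_id == "rare"], "maf")
  expect_equal(rep_$reason[rep_$snp_id == "hwe_bad"], "hwe")
  expect_true(all(c("ok", colnames(filler)) %in%
                    colnames(qc$genotypes$dosage)))
  # sample gate and explicit exclusions
  G2 <- G; G2[1, ] <- NA
  gd2 <- structure(list(dosage = G2, info = gd$info),
                   class = "genotype_dataset")
  qc2 <- qc_genotypes(gd2, exclude_samples = "s002")
  expect_false(qc2$sample_report$kept[1])
  expect_equal(qc2$sample_report$reason[2], "excluded")
})

test_that("a random HWE panel is essentially never dropped by the HWE gate", {
  set.seed(10)
  G <- vapply(runif(300, 0.1, 0.5), function(p) rbinom(500, 2, p),
              numeric(500))
  colnames(G) <- sprintf("snp%03d", 1:300)
  rownames(G) <- sprintf("s%03d", 1:500)
  gd <- structure(list(dosage = G, info = tibble::tibble(
    snp_id = colnames(G), chromosome = "1",
    position = seq_len(300) * 1000)), class = "genotype_dataset")
  qc <- qc_genotypes(gd)
  expect_equal(sum(qc$snp_report$reason == "hwe"), 0)
})

test_that("Tracy-Widom tail probabilities match published thresholds", {
  # 1% and 5% points of the order-1 Tracy-Widom law
  expect_equal(tracy_widom_p(2.0234), 0.01, tolerance = 0.1)
  expect_equal(tracy_widom_p(0.9793), 0.05, tolerance = 0.1)
  expect_true(all(diff(tracy_widom_p(seq(-3, 5, 0.5))) < 0))
})

test_that("PCA outlier detection flags a planted subpopulation", {
  set.seed(11)
  n <- 500; m <- 2000; out_idx <- 1:5
  maf <- runif(m, 0.2, 0.5)
  G <- vapply(maf, function(p) rbinom(n, 2, p), numeric(n))
  for (j in seq_len(m))
    G[out_idx, j] <- rbinom(5, 2, min(maf[j] + 0.3, 0.95))
  rownames(G) <- sprintf("s%03d", 1:n)
  colnames(G) <- sprintf("snp%04d", 1:m)
  gd <- structure(list(dosage = G, info = tibble::tibble(
    snp_id = colnames(G), chromosome = rep(c("1", "2"), length.out = m),
    position = rep(seq_len(m / 2) * 1e4, 2))), class = "genotype_dataset")
  res <- pca_outliers(gd)
  expect_setequal(res$outliers, rownames(G)[out_idx])
  expect_true(res$components$significant[1])
})

test_that("a homogeneous panel yields no PCA outliers", {
  set.seed(12)
  n <- 150; m <- 300
  G <- vapply(runif(m, 0.1, 0.5), function(p) rbinom(n, 2, p), numeric(n))
  rownames(G) <- sprintf("s%03d", 1:n)
  colnames(G) <- sprintf("snp%03d", 1:m)
  gd <- structure(list(dosage = G, info = tibble::tibble(
    snp_id = colnames(G), chromosome = "1", position = seq_len(m) * 1e4)),
    class = "genotype_dataset")
  res <- pca_outliers(gd)
  expect_length(res$outliers, 0)
})
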