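test_that("probe selection keeps the top fraction with deterministic ties", {
  res <- tibble::tibble(probe_id = sprintf("p%03d", 1:100),
                        p_value = rep(seq(0.01, 0.1, length.out = 10), 10))
  sel <- select_probes_by_meta_trait(res, 0.10)
  expect_length(sel, 10)
  # ties broken by probe id: reruns identical
  expect_identical(sel, select_probes_by_meta_trait(res, 0.10))
  # gene collapsing keeps the best probe per gene
  res$gene <- rep(c("g1", "g2"), 50)
  sel2 <- select_probes_by_meta_trait(res, 1)
  expect_length(sel2, 2)
})

test_that("planted module probes dominate the meta-trait ranking", {
  ds <- simulate_dataset(sim_config(
    n_samples = 300, n_probes = 200, n_modules = 1, module_sizes = 20,
    n_snps = 10, n_cis_eqtl = 0, seed = 81,
    trait_loadings = {m <- matrix(0, 7, 1); m[c(3, 5), 1] <- c(0.5, -0.5); m}))
  tr <- standardize_traits(ds$traits)
  Z <- as.matrix(tr[paste0("z_", attr(tr, "trait_names"))])
  expr <- ds$expression$log2
  meta <- purrr::map_dfr(rownames(expr), function(p) {
    w <- fit_meta_lipids(Z, expr[p, ])
    tibble::tibble(probe_id = p, p_value = w$p_value)
  })
  sel <- select_probes_by_meta_trait(meta, 0.10)
  planted <- names(ds$truth$module_assignment)[ds$truth$module_assignment == 1]
  expect_gte(mean(planted %in% sel), 0.9)
})

test_that("scale-free fit scores decaying power laws positively", {
  # exact k^-2 law on a grid (one distinct k per bin)
  grid <- seq(1, 10, length.out = 10)
  k <- rep(grid, times = round(10000 * grid^-2))
  expect_gte(scale_free_fit(k), 0.99)
  # increasing frequency with k scores negative
  k_inc <- rep(1:10, times = 1:10) + runif(55, 0, 0.5)
  expect_lt(scale_free_fit(k_inc), 0)
  expect_error(scale_free_fit(rep(2, 10)), "degenerate")
  expect_error(scale_free_fit(c(1, 2)), "at least 5")
})

test_that("scale-free fit matches a brute-force binned regression oracle", {
  set.seed(83)
  k <- runif(500, 0.5, 20)
  got <- scale_free_fit(k, n_bins = 10)
  bins <- cut(k, 10)
  mk <- tapply(k, bins, mean); fr <- tapply(k, bins, length) / length(k)
  ok <- !is.na(mk) & fr > 0
  orc <- summary(lm(log10(fr[ok]) ~ log10(mk[ok])))
  expect_equal(abs(got), orc$r.squared, tolerance = 1e-12)
  expect_equal(sign(got), -sign(coef(lm(log10(fr[ok]) ~ log10(mk[ok])))[2]),
               ignore_attr = TRUE)
})

test_that("adjacency at power one gives row sums minus the diagonal", {
  set.seed(84)
  X <- matrix(rnorm(50), 10, 5)
  cc <- cor(t(X))
  k <- rowSums(adjacency_matrix(cc, 1))
  expect_equal(k, rowSums(abs(cc)) - 1, tolerance = 1e-12)
  a2 <- adjacency_matrix(cc, 6)
  expect_true(all(a2 >= 0 & a2 <= 1))
  expect_equal(a2, t(a2))
})

test_that("soft power selection returns the smallest qualifying power", {
  ds <- simulate_dataset(small_config(seed = 85))
  cmat <- cor(t(ds$expression$log2))
  sp <- select_soft_power(cmat)
  expect_false(is.na(sp$power))
  tab <- sp$fit_table
  expect_gt(tab$signed_r2[tab$power == sp$power], 0.80)
  smaller <- tab$power < sp$power
  expect_true(all(is.na(tab$signed_r2[smaller]) |
                    tab$signed_r2[smaller] <= 0.80))
  # mean connectivity decreases with power, so smallest qualifying power
  # maximizes connectivity among qualifiers
  expect_true(all(diff(tab$mean_k) < 0))
  expect_error(select_soft_power(matrix(1, 5, 5)), "degenerate")
})

test_that("TOM of a noiseless two-block structure is block-diagonal", {
  blocks <- matrix(0, 30, 30)
  blocks[1:15, 1:15] <- 1; blocks[16:30, 16:30] <- 1
  diag(blocks) <- 0
  tom <- tom_similarity(blocks)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
  expect_equal(tom[1, 20], 0, tolerance = 1e-12)
  expect_equal(tom, t(tom))
})

test_that("module detection recovers noiseless planted blocks exactly", {
  set.seed(86)
  f1 <- rnorm(40); f2 <- rnorm(40)
  X <- rbind(t(replicate(15, 2 + 0.9 * f1)),
             t(replicate(15, 5 - 1.1 * f2)),
             matrix(rnorm(8 * 40), 8, 40))
  rownames(X) <- sprintf("p%02d", 1:38)
  adj <- adjacency_matrix(cor(t(X)), 6)
  mods <- detect_modules(adj)
  expect_equal(max(mods$assignment), 2)
  a <- mods$assignment
  expect_true(all(a[1:15] == a[1]) && all(a[16:30] == a[16]) &&
                a[1] != a[16])
  expect_true(all(a[31:38] == 0))
})

test_that("module detection is invariant to probe order", {
  ds <- simulate_dataset(small_config(seed = 87))
  adj <- adjacency_matrix(cor(t(ds$expression$log2)), 6)
  m1 <- detect_modules(adj)
  perm <- sample(nrow(adj))
  m2 <- detect_modules(adj[perm, perm])
  skip_if_not_installed("mclust")
  common <- names(m1$assignment)
  expect_equal(mclust::adjustedRandIndex(m1$assignment[common],
                                         m2$assignment[common]), 1)
})

test_that("destroying sample structure leaves no modules", {
  set.seed(88)
  n_mod <- vapply(1:3, function(s) {
    ds <- simulate_dataset(small_config(seed = 90 + s))
    X <- ds$expression$log2
    shuffled <- t(apply(X, 1, sample))  # independent shuffle per probe
    adj <- adjacency_matrix(cor(t(shuffled)), 6)
    max(detect_modules(adj)$assignment)
  }, numeric(1))
  expect_true(all(n_mod == 0))
})

test_that("eigengene summarizes a module and respects sign orientation", {
  set.seed(89)
  common <- rnorm(50)
  X <- t(replicate(12, 3 + common))
  e <- module_eigengene(X)
  expect_equal(abs(cor(e, common)), 1, tolerance = 1e-10)
  expect_gt(cor(e, common), 0)  # oriented with members
  expect_equal(sd(e), 1, tolerance = 1e-12)
  # flipping all probes flips the eigengene
  e2 <- module_eigengene(-X)
  expect_equal(as.numeric(e2), as.numeric(-e), tolerance = 1e-10)
  expect_error(module_eigengene(X[1, , drop = FALSE]), "at least 2")
})

test_that("eigengenes track the planted latent factors", {
  ds <- simulate_dataset(small_config(seed = 92))
  ms <- structure(list(assignment = ds$truth$module_assignment),
                  class = "module_set")
  E <- module_eigengenes(ms, ds$expression$log2)
  for (k in 1:2)
    expect_gte(abs(cor(E[k, ], ds$truth$latent_factors[k, ])), 0.9)
})

test_that("module merging joins correlated modules and is idempotent", {
  set.seed(93)
  f <- rnorm(60)
  # two "modules" driven by nearly the same factor, one orthogonal
  X <- rbind(t(replicate(12, 1.0 * f + 0.3 * rnorm(60))),
             t(replicate(12, 0.9 * f + 0.3 * rnorm(60))),
             t(replicate(12, as.numeric(scale(rnorm(60))))))
  rownames(X) <- sprintf("p%02d", 1:36)
  assignment <- setNames(rep(1:3, each = 12), rownames(X))
  ms <- structure(list(assignment = assignment), class = "module_set")
  merged <- merge_modules(ms, X, merge_height = 0.20)
  expect_equal(max(merged$assignment), 2)
  expect_equal(length(unique(merged$assignment[1:24])), 1)
  again <- merge_modules(merged, X, merge_height = 0.20)
  expect_identical(again$assignment, merged$assignment)
  # orthogonal eigengenes never merge
  ms2 <- structure(list(assignment = setNames(rep(1:2, each = 12),
                                              rownames(X)[1:24])),
                   class = "module_set")
  X2 <- X[1:24, ]
  X2[13:24, ] <- t(replicate(12, as.numeric(scale(rnorm(60)))))
  m2 <- merge_modules(ms2, X2, merge_height = 0.20)
  expect_equal(max(m2$assignment), 2)
})

test_that("module count extrapolation reproduces the published arithmetic", {
  ext <- extrapolate_module_alpha(23, 1000, 35419)
  expect_equal(ext$estimated_modules, 814.637, tolerance = 1e-6)
  expect_equal(signif(ext$alpha_adjusted, 3), 6.14e-5)
  triv <- extrapolate_module_alpha(1, 1000, 1000)
  expect_equal(triv$estimated_modules, 1)
  expect_equal(triv$alpha_adjusted, 0.05)
})

test_that("module-trait correlation flags planted associations at the gate", {
  ds <- simulate_dataset(sim_config(
    n_samples = 500, n_probes = 100, n_modules = 1, module_sizes = 25,
    n_snps = 10, n_cis_eqtl = 0, seed = 94,
    trait_loadings = {m <- matrix(0, 7, 1); m[3, 1] <- 0.4; m}))  # HDL row
  tr <- standardize_traits(ds$traits)
  ms <- structure(list(assignment = ds$truth$module_assignment),
                  class = "module_set")
  E <- module_eigengenes(ms, ds$expression$log2)
  mt <- module_trait_correlation(E, tr[paste0("z_", attr(tr, "trait_names"))],
                                 alpha_adj = 6.14e-5)
  hdl <- mt[mt$trait == "z_HDL", ]
  expect_true(hdl$significant)
  expect_gt(abs(hdl$rho), 0.25)
  # eigengene correlated with itself: rho 1, P ~ 0
  self <- module_trait_correlation(E, data.frame(me = E[1, ]))
  expect_equal(self$rho, 1)
  expect_lt(self$p_value, 1e-100)
})

test_that("hub probes carry the trait association (kME vs GS)", {
  set.seed(95)
  n <- 200
  f <- rnorm(n)
  load <- seq(0.3, 0.9, length.out = 20)
  X <- t(vapply(load, function(l) l * f + sqrt(1 - l^2) * rnorm(n),
                numeric(n)))
  rownames(X) <- sprintf("p%02d", 1:20)
  trait <- 0.6 * f + 0.8 * rnorm(n)
  ms <- structure(list(assignment = setNames(rep(1L, 20), rownames(X))),
                  class = "module_set")
  ms$eigengenes <- module_eigengenes(ms, X)
  kg <- module_membership_vs_significance(ms, X, trait)
  expect_equal(nrow(kg), 20)  # background excluded by construction
  expect_gt(attr(kg, "cor_kme_gs"), 0)
  # degenerate: identical probes give constant kME, correlation undefined
  Xc <- t(replicate(5, f)); rownames(Xc) <- paste0("q", 1:5)
  msc <- structure(list(assignment = setNames(rep(1L, 5), rownames(Xc))),
                   class = "module_set")
  msc$eigengenes <- module_eigengenes(msc, Xc)
  kgc <- module_membership_vs_significance(msc, Xc, trait)
  expect_true(is.na(attr(kgc, "cor_kme_gs")))
})

test_that("replication co-expression applies the pairwise Bonferroni gate", {
  set.seed(96)
  f <- rnorm(75)
  X <- rbind(t(replicate(4, 0.9 * f + 0.4 * rnorm(75))),
             matrix(rnorm(3 * 75), 3, 75))
  rownames(X) <- c("HDC", "FCER1A", "GATA2", "CPA3", "r1", "r2", "r3")
  rep_ <- replication_coexpression(X, rownames(X))
  expect_equal(nrow(rep_), choose(7, 2))
  expect_equal(signif(attr(rep_, "gate"), 3), 2.38e-3)
  core <- rep_[rep_$gene_a %in% rownames(X)[1:4] &
                 rep_$gene_b %in% rownames(X)[1:4], ]
  expect_true(all(core$significant))
  # identical profiles give rho 1
  X2 <- rbind(a = f, b = f)
  expect_equal(replication_coexpression(X2, c("a", "b"))$rho, 1)
})
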