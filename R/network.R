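#' Select the probe subset for network construction
#'
#' Probes are ranked by ascending multivariate (meta-trait) association P
#' value and the top fraction retained. When a gene annotation is supplied,
#' probes of the same gene are collapsed to the unique signal with the best
#' P value before ranking. Ties at the boundary are broken deterministically
#' by probe id.
#'
#' @param results Tibble with `probe_id` and `p_value` columns (one row per
#'   probe), optionally a `gene` column for collapsing.
#' @param top_fraction Fraction of probes to keep (default 0.10).
#' @return Character vector of retained probe ids.
#' @export
select_probes_by_meta_trait <- function(results, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if ("gene" %in% names(results) && any(!is.na(results$gene))) {
    results <- results |>
      dplyr::group_by(.data$gene) |>
      dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  results <- dplyr::arrange(results, .data$p_value, .data$probe_id)
  utils::head(results$probe_id, ceiling(top_fraction * nrow(results)))
}

#' Signed scale-free topology fit
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins,
#' regresses log10 mean frequency on log10 mean connectivity, and returns
#' the coefficient of determination signed by the negative of the slope's
#' sign, so that decaying (power-law-like) degree distributions score
#' positive.
#'
#' @param k Positive connectivities (>= 5 values).
#' @param n_bins Number of bins (default 10).
#' @return Signed R-squared in [-1, 1].
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 5) stop("need at least 5 positive connectivities",
                          call. = FALSE)
  if (diff(range(k)) == 0)
    stop("degenerate connectivity distribution: all values equal",
         call. = FALSE)
  bins <- cut(k, n_bins)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq) & freq > 0
  if (sum(ok) < 3)
    stop("degenerate connectivity distribution: too few occupied bins",
         call. = FALSE)
  fit <- lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(coef(fit)[2]) * r2)
}

#' Soft threshold power selection
#'
#' For each candidate power beta, forms the weighted adjacency
#' `a_ij = |cor_ij|^beta` (diagonal excluded), computes node connectivities
#' `k_i = sum_j a_ij`, and assesses the signed scale-free topology fit. The
#' chosen beta is the smallest power whose signed R-squared exceeds
#' `r2_min` (default 0.80): among qualifying powers, the smallest maximizes
#' mean connectivity, honouring both selection criteria.
#'
#' @param cor_mat Square symmetric correlation matrix.
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_min Scale-free fit requirement.
#' @param n_bins Bins passed to [scale_free_fit()].
#' @return List with `power` (chosen beta, `NA` if none qualifies) and
#'   `fit_table` (tibble: `power`, `signed_r2`, `mean_k`, `median_k`,
#'   `max_k`).
#' @export
select_soft_power <- function(cor_mat, powers = 1:20, r2_min = 0.80,
                              n_bins = 10) {
  cor_mat <- as.matrix(cor_mat)
  stopifnot(nrow(cor_mat) == ncol(cor_mat))
  ac <- abs(cor_mat)
  diag(ac) <- 0
  tab <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(ac^b)
    r2 <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NA_real_)
    tibble::tibble(power = b, signed_r2 = r2, mean_k = mean(k),
                   median_k = median(k), max_k = max(k))
  })
  if (all(is.na(tab$signed_r2)))
    stop("scale-free fit undefined for every candidate power ",
         "(degenerate connectivity distribution)", call. = FALSE)
  qual <- tab$power[!is.na(tab$signed_r2) & tab$signed_r2 > r2_min]
  list(power = if (length(qual)) min(qual) else NA_integer_, fit_table = tab)
}

#' Weighted adjacency from correlations
#'
#' Unsigned soft-threshold adjacency `a_ij = |cor_ij|^beta`, diagonal set to
#' zero.
#'
#' @param cor_mat Correlation matrix.
#' @param power Soft threshold beta.
#' @return Adjacency matrix in [0, 1].
#' @export
adjacency_matrix <- function(cor_mat, power) {
  a <- abs(as.matrix(cor_mat))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM similarity: `tom_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij)` with `L = A %*% A` (shared-neighbour weight) and unit diagonal.
#'
#' @param adjacency Adjacency matrix with zero diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' Module detection by hierarchical clustering and branch cutting
#'
#' Probes are clustered by average linkage on a dissimilarity (1 - TOM by
#' default, 1 - adjacency optionally) and modules are read off the
#' dendrogram branches. By default a branch with at least
#' `min_module_size` leaves becomes a module when it is *persistent*: the
#' gap between the height at which the branch completes and the height at
#' which it is absorbed into a larger cluster covers at least `persistence`
#' (default 0.7) of the branch's remaining headroom
#' `(h_join - h_branch) / (1 - h_branch)`. Tightly co-expressed branches
#' complete early and survive almost all the way to the top of the tree,
#' while background probes coalesce in a dense shelf of merges just below
#' the maximum dissimilarity where no branch persists. Among nested
#' persistent branches the largest is kept. Alternatively a classical
#' constant-height cut is applied when `cut_height` is given. Probes in no
#' module are labelled 0 (background); modules are labelled 1, 2, ... by
#' decreasing size.
#'
#' @param adjacency Adjacency matrix (values in [0, 1], zero diagonal) with
#'   probe ids as dimnames.
#' @param dissimilarity `"tom"` (default) or `"adjacency"`.
#' @param min_module_size Minimum leaves per module (default 10).
#' @param persistence Branch persistence threshold in (0, 1).
#' @param cut_height Optional absolute cut height; when given, branches
#'   below this height with at least `min_module_size` leaves become
#'   modules (constant-height variant).
#' @return A list of class `module_set`: `assignment` (named integer vector,
#'   0 = background), `dendrogram` (hclust), `cut_height` (`NA` for the
#'   branch-persistence rule).
#' @export
detect_modules <- function(adjacency, dissimilarity = c("tom", "adjacency"),
                           min_module_size = 10, persistence = 0.7,
                           cut_height = NULL) {
  dissimilarity <- match.arg(dissimilarity)
  A <- as.matrix(adjacency)
  ids <- rownames(A) %||% sprintf("probe_%04d", seq_len(nrow(A)))
  if (nrow(A) < min_module_size) {
    return(structure(list(
      assignment = setNames(integer(nrow(A)), ids),
      dendrogram = NULL, cut_height = NA_real_), class = "module_set"))
  }
  sim <- if (dissimilarity == "tom") tom_similarity(A) else A
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "average")

  if (!is.null(cut_height)) {
    cl <- stats::cutree(hc, h = cut_height)
  } else {
    cl <- .persistent_branches(hc, min_module_size, persistence)
  }
  sizes <- table(cl[cl != 0])
  mods <- names(sizes)[sizes >= min_module_size]
  mods <- mods[order(-sizes[mods])]
  assignment <- setNames(integer(length(cl)), ids)
  for (i in seq_along(mods)) assignment[cl == as.integer(mods[i])] <- i
  structure(list(assignment = assignment, dendrogram = hc,
                 cut_height = if (is.null(cut_height)) NA_real_
                 else cut_height), class = "module_set")
}

# label leaves by maximal persistent branches (0 = unassigned)
.persistent_branches <- function(hc, min_size, persistence) {
  n <- length(hc$height) + 1
  m <- hc$merge
  h <- hc$height
  size <- numeric(n - 1)
  for (i in seq_len(n - 1))
    size[i] <- sum(ifelse(m[i, ] < 0, 1, size[pmax(m[i, ], 1)]))
  parent <- rep(NA_integer_, n - 1)
  for (j in seq_len(n - 1)) for (k in m[j, ]) if (k > 0) parent[k] <- j
  headroom <- pmax(1 - h, .Machine$double.eps)
  cscore <- (h[parent] - h) / headroom
  ok <- which(!is.na(cscore) & cscore >= persistence & size >= min_size)

  labels <- integer(n)  # per leaf
  if (!length(ok)) return(labels)
  leaves_of <- function(i) {
    out <- integer(0); stack <- i
    while (length(stack)) {
      j <- stack[1]; stack <- stack[-1]
      for (k in m[j, ]) {
        if (k < 0) out <- c(out, -k) else stack <- c(stack, k)
      }
    }
    out
  }
  lab <- 0L
  # most persistent branch wins among nested candidates; ties broken by
  # size then node index for determinism
  for (i in ok[order(-cscore[ok], -size[ok], ok)]) {
    lv <- leaves_of(i)
    if (all(labels[lv] == 0)) {
      lab <- lab + 1L
      labels[lv] <- lab
    }
  }
  labels
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- max(x$assignment)
  cat("<module_set> ", length(x$assignment), " probes, ", n_mod,
      " modules (", sum(x$assignment == 0), " background)\n", sep = "")
  invisible(x)
}

#' Module eigengene
#'
#' The module's summary profile: probes are standardized across samples and
#' the first right-singular vector of the resulting submatrix is taken,
#' scaled to unit variance and sign-oriented so that its mean correlation
#' with the member probes is positive.
#'
#' @param expr_module Probes x samples expression submatrix (>= 2 probes).
#' @return Numeric vector (one value per sample) with attribute
#'   `var_explained`.
#' @export
module_eigengene <- function(expr_module) {
  X <- as.matrix(expr_module)
  if (nrow(X) < 2) stop("a module needs at least 2 probes", call. = FALSE)
  Xs <- t(scale(t(X)))
  Xs[is.na(Xs)] <- 0
  sv <- svd(Xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- e / sd(e)
  cors <- suppressWarnings(cor(e, t(X)))
  m <- mean(cors, na.rm = TRUE)
  if (!is.na(m) && m < 0) e <- -e
  attr(e, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  e
}

#' Eigengenes for every module in a module set
#'
#' @param modules A `module_set`.
#' @param expression Probes x samples matrix covering the assigned probes.
#' @return Modules x samples matrix (rownames `ME1`, `ME2`, ...).
#' @export
module_eigengenes <- function(modules, expression) {
  n_mod <- max(modules$assignment)
  if (n_mod == 0) return(matrix(nrow = 0, ncol = ncol(expression)))
  E <- t(vapply(seq_len(n_mod), function(m) {
    probes <- names(modules$assignment)[modules$assignment == m]
    module_eigengene(expression[probes, , drop = FALSE])
  }, numeric(ncol(expression))))
  dimnames(E) <- list(paste0("ME", seq_len(n_mod)), colnames(expression))
  E
}

#' Merge highly correlated modules
#'
#' Module eigengenes are clustered by average linkage on `1 - cor`; clusters
#' of eigengenes joining below `merge_height` (default 0.20) are merged,
#' eigengenes are recomputed, and the procedure iterates until no further
#' merge occurs (so it is idempotent at a fixed height).
#'
#' @param modules A `module_set`.
#' @param expression Probes x samples matrix.
#' @param merge_height Dendrogram height below which modules merge.
#' @return A `module_set` with relabelled assignment and an `eigengenes`
#'   element.
#' @export
merge_modules <- function(modules, expression, merge_height = 0.20) {
  assignment <- modules$assignment
  repeat {
    n_mod <- max(assignment)
    if (n_mod <= 1) break
    tmp <- structure(list(assignment = assignment), class = "module_set")
    ME <- module_eigengenes(tmp, expression)
    d <- stats::as.dist(1 - cor(t(ME)))
    hc <- stats::hclust(d, method = "average")
    grp <- stats::cutree(hc, h = merge_height)
    if (max(grp) == n_mod) break
    new_assignment <- assignment
    for (g in seq_len(max(grp))) {
      members <- which(grp == g)
      new_assignment[assignment %in% members] <- g
    }
    # relabel by decreasing size
    sizes <- table(new_assignment[new_assignment > 0])
    ord <- as.integer(names(sizes)[order(-sizes)])
    relab <- match(new_assignment, ord)
    relab[is.na(relab)] <- 0
    assignment <- setNames(as.integer(relab), names(assignment))
  }
  out <- structure(list(assignment = assignment,
                        dendrogram = modules$dendrogram,
                        cut_height = modules$cut_height),
                   class = "module_set")
  out$eigengenes <- module_eigengenes(out, expression)
  out
}

#' Module-trait correlation table
#'
#' Spearman rank correlation (with the n - 2 df t-test of
#' [spearman_test()]) between each module eigengene and each standardized
#' trait; significance is gated at `alpha_adj`, typically the extrapolated
#' module-count level from [extrapolate_module_alpha()].
#'
#' @param eigengenes Modules x samples matrix.
#' @param traits Standardized trait tibble/matrix (samples x traits).
#' @param alpha_adj Significance gate applied to nominal P values.
#' @return Tibble: `module`, `trait`, `rho`, `p_value`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits, alpha_adj = 0.05) {
  traits <- as.data.frame(traits)
  purrr::map_dfr(rownames(eigengenes), function(m) {
    purrr::map_dfr(names(traits), function(tr) {
      st <- spearman_test(eigengenes[m, ], traits[[tr]])
      tibble::tibble(module = m, trait = tr, rho = st$rho,
                     p_value = st$p_value,
                     significant = !is.na(st$p_value) & st$p_value < alpha_adj)
    })
  })
}

#' Extrapolated module count and adjusted significance level
#'
#' When modules are detected on a subset of probes, the expected number of
#' modules in the full dataset is extrapolated proportionally
#' (`n_modules_subset * n_probes_total / n_probes_subset`) and the
#' module-trait significance level is `alpha` divided by that estimate.
#'
#' @param n_modules_subset Modules found in the subset.
#' @param n_probes_subset Probes in the subset.
#' @param n_probes_total Probes in the full dataset.
#' @param alpha Base significance level (default 0.05).
#' @return List with `estimated_modules` and `alpha_adjusted`.
#' @export
extrapolate_module_alpha <- function(n_modules_subset, n_probes_subset,
                                     n_probes_total, alpha = 0.05) {
  stopifnot(n_modules_subset > 0, n_probes_subset > 0, n_probes_total > 0)
  est <- n_modules_subset * n_probes_total / n_probes_subset
  list(estimated_modules = est, alpha_adjusted = alpha / est)
}

#' Module membership versus gene significance
#'
#' Within one module: module membership `kME` is the correlation of each
#' member probe with the module eigengene (intramodular connectivity), and
#' gene significance `GS` is the absolute correlation of the probe with the
#' trait. Their correlation summarizes whether hub genes carry the trait
#' association. Background probes are excluded.
#'
#' @param modules A merged `module_set` with `eigengenes`.
#' @param expression Probes x samples matrix.
#' @param trait Per-sample trait vector.
#' @param module Module label (integer) to report.
#' @return Tibble (`probe_id`, `kME`, `GS`) with attribute `cor_kme_gs`
#'   (`NA` when degenerate, e.g. constant kME).
#' @export
module_membership_vs_significance <- function(modules, expression, trait,
                                              module = 1) {
  probes <- names(modules$assignment)[modules$assignment == module]
  if (!length(probes)) stop("empty module", call. = FALSE)
  e <- modules$eigengenes[paste0("ME", module), ]
  kme <- drop(cor(t(expression[probes, , drop = FALSE]), e))
  gs <- abs(drop(cor(t(expression[probes, , drop = FALSE]), trait)))
  out <- tibble::tibble(probe_id = probes, kME = kme, GS = gs)
  r <- if (sd(kme) == 0 || sd(gs) == 0) NA_real_ else cor(kme, gs)
  attr(out, "cor_kme_gs") <- r
  out
}

#' Pairwise co-expression replication test
#'
#' Tests every unordered pair of the given genes for co-expression in an
#' independent expression matrix using the Spearman rank correlation with
#' t-test P values, gated at the Bonferroni level `alpha /
#' choose(n_genes, 2)`.
#'
#' @param expression Probes/genes x samples matrix of the replication
#'   dataset.
#' @param genes Character vector of gene/probe ids present in `expression`.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble (`gene_a`, `gene_b`, `rho`, `p_value`, `significant`) with
#'   attribute `gate`.
#' @export
replication_coexpression <- function(expression, genes, alpha = 0.05) {
  stopifnot(all(genes %in% rownames(expression)), length(genes) >= 2)
  pairs <- utils::combn(genes, 2)
  gate <- alpha / ncol(pairs)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    st <- spearman_test(expression[pairs[1, j], ], expression[pairs[2, j], ])
    tibble::tibble(gene_a = pairs[1, j], gene_b = pairs[2, j], rho = st$rho,
                   p_value = st$p_value, significant = st$p_value < gate)
  })
  attr(out, "gate") <- gate
  out
}
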