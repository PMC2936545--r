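#' Specify a structural equation path model
#'
#' Describes a recursive path diagram over observed variables and (at most
#' one) latent variable. Every observed variable receives a free (residual)
#' variance; a latent variable has its variance fixed to 1 with free
#' loadings, which identifies the scale of its paths.
#'
#' @param paths Two-column matrix or data frame (`from`, `to`) of directed
#'   paths with free coefficients.
#' @param latents Character vector of latent variable names (at most one
#'   supported).
#' @param covs Optional two-column matrix of variable pairs with a free
#'   residual covariance (e.g. a correlated-residual confounder).
#' @return An object of class `sem_model`.
#' @export
sem_model <- function(paths, latents = character(), covs = NULL) {
  paths <- as.data.frame(paths)
  names(paths) <- c("from", "to")
  paths$from <- as.character(paths$from)
  paths$to <- as.character(paths$to)
  if (any(paths$to %in% latents))
    stop("latent variables cannot be endogenous here", call. = FALSE)
  if (!is.null(covs)) {
    covs <- as.data.frame(covs)
    names(covs) <- c("a", "b")
  }
  structure(list(paths = paths, latents = latents, covs = covs),
            class = "sem_model")
}

# implied covariance of the observed block under RAM parameterization:
# Sigma = F (I - A)^-1 S (I - A)^-T F', A = path matrix, S = diagonal
# (residual) variances with latent variances fixed at 1.
.sem_implied <- function(model, theta, obs_vars) {
  vars <- c(obs_vars, model$latents)
  q <- length(vars)
  np <- nrow(model$paths)
  A <- matrix(0, q, q, dimnames = list(vars, vars))
  for (i in seq_len(np))
    A[model$paths$to[i], model$paths$from[i]] <- theta[i]
  Svec <- c(exp(theta[np + seq_along(obs_vars)]),
            rep(1, length(model$latents)))
  Smat <- diag(Svec, q)
  dimnames(Smat) <- list(vars, vars)
  nc <- if (is.null(model$covs)) 0 else nrow(model$covs)
  for (i in seq_len(nc)) {
    v <- theta[np + length(obs_vars) + i]
    Smat[model$covs$a[i], model$covs$b[i]] <- v
    Smat[model$covs$b[i], model$covs$a[i]] <- v
  }
  IA <- solve(diag(q) - A)
  full <- IA %*% Smat %*% t(IA)
  full[obs_vars, obs_vars, drop = FALSE]
}

# ML discrepancy F = log det Sigma + tr(S Sigma^-1) - log det S - p
.sem_discrepancy <- function(model, theta, S, obs_vars) {
  Sigma <- .sem_implied(model, theta, obs_vars)
  chS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(chS)) return(1e10)
  logdet <- 2 * sum(log(diag(chS)))
  logdet + sum(diag(S %*% chol2inv(chS))) -
    determinant(S)$modulus[1] - length(obs_vars)
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the maximum-likelihood discrepancy between the sample
#' covariance and the model-implied covariance (quasi-Newton, residual
#' variances on the log scale). The model chi-square is `(n - 1) * F_min`
#' with `df = p(p+1)/2 - #free parameters`; the fit P value is the upper
#' chi-square tail (a *large* P indicates the model is consistent with the
#' data). Path Z statistics are estimates divided by standard errors from
#' the inverse information matrix.
#'
#' @param model A [sem_model()].
#' @param S Sample covariance matrix of the observed variables (positive
#'   definite, with dimnames).
#' @param n Sample size.
#' @param se Compute standard errors (numerical Hessian); disable for speed
#'   when only the fit statistic is needed.
#' @return An object of class `ll_sem`: `chisq`, `df`, `p_value`, `fmin`,
#'   `estimates` tibble (`from`, `to`, `estimate`, `se`, `z`), `converged`.
#'   Supports [tidy()] and [glance()].
#' @export
fit_sem <- function(model, S, n, se = TRUE) {
  obs_vars <- rownames(S)
  stopifnot(!is.null(obs_vars), isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-10 * max(diag(S)))
    stop("covariance matrix is not positive definite", call. = FALSE)
  p <- length(obs_vars)
  np <- nrow(model$paths)
  nc <- if (is.null(model$covs)) 0 else nrow(model$covs)
  n_free <- np + p + nc
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("model is not identified (df < 0)", call. = FALSE)

  # start paths from marginal covariances, residual variances at half the
  # observed variances
  theta0 <- c(
    vapply(seq_len(np), function(i) {
      f <- model$paths$from[i]; t_ <- model$paths$to[i]
      if (f %in% obs_vars) S[t_, f] / S[f, f] else 0.3
    }, numeric(1)),
    log(pmax(diag(S) / 2, 1e-3)),
    rep(0, nc))

  opt <- optim(theta0, function(th) .sem_discrepancy(model, th, S, obs_vars),
               method = "BFGS", hessian = se,
               control = list(maxit = 500, reltol = 1e-10))
  fmin <- max(opt$value, 0)
  chisq <- max((n - 1) * fmin, 0)
  p_value <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)

  se_vec <- rep(NA_real_, np)
  acov <- if (!se) NULL else
    tryCatch((2 / (n - 1)) * solve(opt$hessian), error = function(e) NULL)
  if (!is.null(acov)) {
    d <- diag(acov)[seq_len(np)]
    d[!is.finite(d) | d <= 0] <- NA_real_
    se_vec <- sqrt(d)
  }
  est <- tibble::tibble(from = model$paths$from, to = model$paths$to,
                        estimate = opt$par[seq_len(np)], se = se_vec,
                        z = opt$par[seq_len(np)] / se_vec)
  structure(list(chisq = chisq, df = df, p_value = p_value, fmin = fmin,
                 estimates = est, converged = opt$convergence == 0, n = n),
            class = "ll_sem")
}

#' @export
print.ll_sem <- function(x, ...) {
  cat(sprintf("SEM fit: chi-square = %.4f on %d df, P = %.4g%s\n",
              x$chisq, x$df, x$p_value,
              if (!x$converged) " (NOT converged)" else ""))
  print(x$estimates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ll_sem <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.ll_sem <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p_value = x$p_value,
                 fmin = x$fmin, converged = x$converged, n = x$n)
}

# the five competing path models over (MA, A, B, MB) for orienting A -> B
.leo_models <- function() {
  list(
    causal = sem_model(rbind(c("MA", "A"), c("A", "B"), c("MB", "B"))),
    reactive = sem_model(rbind(c("MB", "B"), c("B", "A"), c("MA", "A"))),
    confounded = sem_model(rbind(c("MA", "A"), c("MB", "B")),
                           covs = rbind(c("A", "B"))),
    collider_a = sem_model(rbind(c("MA", "A"), c("MB", "A"), c("A", "B"))),
    collider_b = sem_model(rbind(c("MA", "B"), c("MB", "B"), c("B", "A"))))
}

#' LEO.NB.OCA edge-orienting score
#'
#' Orients the edge A -> B using orthogonal causal anchors: SNP `M_A`
#' anchoring node A and SNP `M_B` anchoring node B. Five competing path
#' models over (M_A, A, B, M_B) are fitted by maximum likelihood — causal
#' (M_A->A->B<-M_B), reactive (M_A->A<-B<-M_B), a confounder model
#' (anchors retained, free residual covariance between A and B standing in
#' for a shared hidden cause), and the two collider variants in which both
#' anchors feed a single node that then drives the other. The LEO score is the log10 ratio of the causal model's
#' fit P value to the best (largest) competing P value; a score of at least
#' `leo_threshold` (0.3, i.e. the causal model fits at least twice as well)
#' declares the orientation. The edge itself requires |Pearson(A, B)| above
#' `edge_threshold` (0.3) and a significant causal path (|Z| > 1.96), and a
#' causal-model fit P value at or below 0.05 flags the model as a poor
#' absolute fit even when best.
#'
#' @param A,B Node values per sample (trait Z-scores or expression).
#' @param M_A,M_B Anchor SNP dosages per sample.
#' @param edge_threshold,leo_threshold Orientation gates.
#' @param standardize Standardize all four variables first (default TRUE).
#' @return A one-row tibble of class `ll_leo`: `edge`, `leo_score`,
#'   `model_p` (causal-model fit P), `pearson`, `path_z`, `verdict`
#'   (`"causal"`, `"inconclusive"` or `"rejected"`), `poor_fit`,
#'   `weak_anchor`, plus the per-model fit P values nested in
#'   `model_fits`.
#' @export
leo_nb_oca <- function(A, B, M_A, M_B, edge_threshold = 0.3,
                       leo_threshold = 0.3, standardize = TRUE) {
  dat <- cbind(MA = M_A, A = A, B = B, MB = M_B)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (standardize) dat <- scale(dat)
  S <- cov(dat)
  pearson <- cor(dat[, "A"], dat[, "B"])
  weak <- abs(cor(dat[, "MA"], dat[, "A"])) < 1e-8 ||
    abs(cor(dat[, "MB"], dat[, "B"])) < 1e-8
  if (abs(cor(dat[, "MA"], dat[, "MB"])) > 0.95)
    stop("anchors M_A and M_B are (near-)collinear; LEO.NB.OCA requires ",
         "orthogonal causal anchors", call. = FALSE)
  mods <- .leo_models()
  fits <- purrr::imap(mods, function(m, nm)
    fit_sem(m, S = S, n = n, se = nm == "causal"))
  pvals <- vapply(fits, `[[`, numeric(1), "p_value")
  rivals <- pvals[setdiff(names(pvals), "causal")]
  leo <- log10(max(pvals[["causal"]], 1e-300) /
                 max(max(rivals), 1e-300))
  est <- fits$causal$estimates
  path_z <- est$z[est$from == "A" & est$to == "B"]
  verdict <- if (abs(pearson) <= edge_threshold) "rejected"
  else if (leo >= leo_threshold && !is.na(path_z) && abs(path_z) > 1.96)
    "causal" else "inconclusive"
  out <- tibble::tibble(
    edge = "A->B", leo_score = leo, model_p = pvals[["causal"]],
    pearson = pearson, path_z = path_z %||% NA_real_, verdict = verdict,
    poor_fit = pvals[["causal"]] <= 0.05, weak_anchor = weak,
    model_fits = list(tibble::tibble(model = names(pvals), p_value = pvals)))
  class(out) <- c("ll_leo", class(out))
  out
}

#' Orient a network of anchored nodes
#'
#' Enumerates all node pairs whose absolute Pearson correlation exceeds
#' `edge_threshold`, runs [leo_nb_oca()] in both directions for each, and
#' reports the directed-edge table: LEO score, causal-model fit P, Pearson
#' edge score, path Z statistic and the verdict (`"causal"` when the LEO
#' and path-Z gates pass; edges whose causal-model P is at or below 0.05
#' are additionally flagged as poor fits).
#'
#' @param nodes Samples x nodes data frame or matrix of node values.
#' @param anchors Named list mapping each node name to its anchor SNP
#'   dosage vector (every node needs an anchor).
#' @param edge_threshold,leo_threshold Gates as in [leo_nb_oca()].
#' @return Tibble with one row per ordered pair passing the edge gate:
#'   `edge`, `a`, `b`, `leo_score`, `model_p`, `pearson`, `path_z`,
#'   `verdict`, `poor_fit`.
#' @export
orient_network <- function(nodes, anchors, edge_threshold = 0.3,
                           leo_threshold = 0.3) {
  nodes <- as.data.frame(nodes)
  missing_anchor <- setdiff(names(nodes), names(anchors))
  if (length(missing_anchor))
    stop("nodes without anchors: ", paste(missing_anchor, collapse = ", "),
         call. = FALSE)
  nms <- names(nodes)
  out <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i >= j) next
    a <- nms[i]; b <- nms[j]
    if (abs(cor(nodes[[a]], nodes[[b]])) <= edge_threshold) next
    for (dir in list(c(a, b), c(b, a))) {
      r <- leo_nb_oca(nodes[[dir[1]]], nodes[[dir[2]]],
                      anchors[[dir[1]]], anchors[[dir[2]]],
                      edge_threshold, leo_threshold)
      r$edge <- paste0(dir[1], "->", dir[2])
      r$a <- dir[1]; r$b <- dir[2]
      out[[length(out) + 1]] <- r
    }
  }
  if (!length(out))
    return(tibble::tibble(edge = character(), a = character(),
                          b = character(), leo_score = numeric(),
                          model_p = numeric(), pearson = numeric(),
                          path_z = numeric(), verdict = character(),
                          poor_fit = logical()))
  dplyr::bind_rows(out)[, c("edge", "a", "b", "leo_score", "model_p",
                            "pearson", "path_z", "verdict", "poor_fit")]
}

#' Automatic anchor SNP selection
#'
#' Selects causal-anchor SNPs for each node from a candidate pool. The
#' greedy method takes the single best-associated SNP per node; the
#' forward-stepwise method adds SNPs while the partial-F P value of the
#' entering SNP stays below `enter_p` (default 0.05). Each selected SNP is
#' cross-checked against all nodes: it must associate most strongly (by
#' nominal P) with the node it anchors, otherwise it is flagged.
#'
#' @param nodes Samples x nodes data frame of node values.
#' @param snps Samples x SNPs dosage matrix (the candidate pool; must be
#'   non-empty).
#' @param method `"greedy"` or `"forward-stepwise"`.
#' @param enter_p Stepwise entry threshold.
#' @return Tibble: `node`, `snp_id`, `p_value`, `cross_assigned` (TRUE when
#'   the SNP associates more strongly with a different node).
#' @export
anchor_autoselect <- function(nodes, snps,
                              method = c("greedy", "forward-stepwise"),
                              enter_p = 0.05) {
  method <- match.arg(method)
  nodes <- as.data.frame(nodes)
  snps <- as.matrix(snps)
  if (ncol(snps) == 0) stop("empty candidate SNP pool", call. = FALSE)
  if (is.null(colnames(snps)))
    colnames(snps) <- sprintf("snp_%04d", seq_len(ncol(snps)))
  # nominal association P of every SNP with every node (simple regression)
  pmat <- vapply(names(nodes), function(nd) {
    y <- nodes[[nd]]
    apply(snps, 2, function(g) {
      if (var(g) == 0) return(1)
      summary(lm(y ~ g))$coefficients["g", 4]
    })
  }, numeric(ncol(snps)))
  pmat <- matrix(pmat, ncol = length(nodes),
                 dimnames = list(colnames(snps), names(nodes)))

  out <- purrr::map_dfr(names(nodes), function(nd) {
    y <- nodes[[nd]]
    if (method == "greedy") {
      best <- which.min(pmat[, nd])
      sel <- tibble::tibble(node = nd, snp_id = rownames(pmat)[best],
                            p_value = pmat[best, nd])
    } else {
      chosen <- character()
      current <- lm(y ~ 1)
      repeat {
        remaining <- setdiff(colnames(snps), chosen)
        if (!length(remaining)) break
        pvs <- vapply(remaining, function(s) {
          fit <- lm(y ~ cbind(snps[, chosen, drop = FALSE],
                              snps[, s, drop = FALSE]))
          a <- anova(current, fit)
          a$`Pr(>F)`[2]
        }, numeric(1))
        if (min(pvs, na.rm = TRUE) >= enter_p) break
        s <- remaining[which.min(pvs)]
        chosen <- c(chosen, s)
        current <- lm(y ~ snps[, chosen, drop = FALSE])
      }
      if (!length(chosen)) {
        best <- which.min(pmat[, nd])
        chosen <- rownames(pmat)[best]
      }
      sel <- tibble::tibble(node = nd, snp_id = chosen,
                            p_value = pmat[chosen, nd])
    }
    sel
  })
  out$cross_assigned <- vapply(seq_len(nrow(out)), function(i) {
    row <- pmat[out$snp_id[i], , drop = FALSE]
    colnames(row)[which.min(row)] != out$node[i]
  }, logical(1))
  out
}
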