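#' Bonferroni correction
#'
#' @param p Nominal P value(s).
#' @param m Number of tests (>= 1).
#' @return `min(1, p * m)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Spearman rank correlation with t-test P value
#'
#' Ranks both vectors (midranks for ties), computes the Pearson correlation
#' of the ranks, and tests it with `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on n - 2 degrees of freedom (two-sided), the large-sample convention for
#' rank correlations.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); pairs with missing
#'   values are dropped.
#' @return A tibble with `rho`, `statistic`, `df`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- cor(rank(x), rank(y))
  if (is.na(rho))
    return(tibble::tibble(rho = NA_real_, statistic = NA_real_,
                          df = n - 2, p_value = NA_real_, n = n))
  if (abs(rho) >= 1) {
    stat <- sign(rho) * Inf; pv <- 0
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    pv <- 2 * pt(-abs(stat), df = n - 2)
  }
  tibble::tibble(rho = rho, statistic = stat, df = n - 2, p_value = pv, n = n)
}

# Design matrix from a covariate tibble: binary/logical/factor columns become
# dummies, numeric pass through. Collinear columns are dropped with a warning.
.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(nrow = n, ncol = 0))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)] - 1
    keep <- keep[keep > 0]
    warning("dropping collinear covariate column(s): ",
            paste(colnames(X)[-keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Univariate trait-expression association
#'
#' For each probe, fits an ordinary least squares regression of the
#' standardized trait on the probe's log2-normalized expression plus the
#' trait's covariates (age, medications, alcohol as configured), and reports
#' the slope on expression with its 95% confidence interval, the nominal P
#' value of the no-association test, and the Bonferroni-corrected P over
#' `m_tests` probes. The significance gate is nominal P < `alpha / m_tests`.
#'
#' @param trait_z Standardized trait vector (one value per sample).
#' @param expression Probes x samples log2 expression matrix.
#' @param covariates Tibble of per-sample covariates (may be `NULL`).
#' @param m_tests Number of tests for the Bonferroni correction; defaults to
#'   the number of probes supplied.
#' @param alpha Family-wise error target (default 0.05).
#' @param direction `"trait_on_expression"` (default) or
#'   `"expression_on_trait"`; the regression can be run either way round.
#' @return A tibble (one row per probe): `probe_id`, `beta`, `ci_lower`,
#'   `ci_upper`, `p_value`, `p_corrected`, `significant`, `n`.
#' @export
fit_trait_expression <- function(trait_z, expression, covariates = NULL,
                                 m_tests = nrow(expression), alpha = 0.05,
                                 direction = c("trait_on_expression",
                                               "expression_on_trait")) {
  direction <- match.arg(direction)
  expression <- as.matrix(expression)
  n <- ncol(expression)
  stopifnot(length(trait_z) == n)
  C <- .covariate_matrix(covariates, n)
  if (n <= ncol(C) + 2) stop("more parameters than samples", call. = FALSE)
  gate <- alpha / m_tests
  res <- purrr::map_dfr(seq_len(nrow(expression)), function(i) {
    e <- expression[i, ]
    if (direction == "trait_on_expression") {
      y <- trait_z; x <- e
    } else {
      y <- e; x <- trait_z
    }
    X <- cbind(`(Intercept)` = 1, x = x, C)
    fit <- stats::lm.fit(X, y)
    rdf <- n - fit$rank
    rss <- sum(fit$residuals^2)
    XtXi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / rdf * XtXi[2, 2])
    b <- fit$coefficients["x"]
    tstat <- b / se
    pv <- 2 * pt(-abs(tstat), rdf)
    tq <- stats::qt(0.975, rdf)
    tibble::tibble(probe_id = rownames(expression)[i] %||% as.character(i),
                   beta = unname(b), ci_lower = unname(b - tq * se),
                   ci_upper = unname(b + tq * se), p_value = pv,
                   p_corrected = bonferroni(pv, m_tests),
                   significant = pv < gate, n = n)
  })
  attr(res, "gate") <- gate
  attr(res, "m_tests") <- m_tests
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-type covariates from marker gene sets
#'
#' For each cell type, every marker probe is standardized across samples and
#' the per-sample mean of these standard scores is returned as the cell
#' type's covariate, a proxy for the relative abundance of that cell
#' population.
#'
#' @param expression Probes x samples log2 expression matrix.
#' @param marker_sets Named list of character vectors of probe ids.
#' @return Tibble, one column per cell type (zero-mean by construction) plus
#'   `sample_id`.
#' @export
celltype_covariates <- function(expression, marker_sets) {
  stopifnot(is.list(marker_sets), length(marker_sets) > 0)
  out <- tibble::tibble(
    sample_id = colnames(expression) %||%
      sprintf("sample_%03d", seq_len(ncol(expression))))
  for (ct in names(marker_sets)) {
    markers <- marker_sets[[ct]]
    if (length(markers) == 0) stop("empty marker set: ", ct, call. = FALSE)
    present <- markers %in% rownames(expression)
    if (!all(present)) {
      message("celltype_covariates: skipping absent marker(s) for ", ct, ": ",
              paste(markers[!present], collapse = ", "))
      markers <- markers[present]
    }
    if (length(markers) == 0) stop("no markers left for ", ct, call. = FALSE)
    Z <- t(scale(t(expression[markers, , drop = FALSE])))
    out[[ct]] <- colMeans(Z)
  }
  out
}

# Rao's F approximation for Wilks' lambda with hypothesis df h, p responses,
# error df ve. Exact when min(p, h) <= 2.
.wilks_rao <- function(lambda, p, h, ve) {
  t <- if (p^2 + h^2 - 5 > 0) sqrt((p^2 * h^2 - 4) / (p^2 + h^2 - 5)) else 1
  w <- ve - (p - h + 1) / 2
  df1 <- p * h
  df2 <- w * t - (p * h - 2) / 2
  lam_t <- lambda^(1 / t)
  f <- (1 - lam_t) / lam_t * df2 / df1
  list(f = f, df1 = df1, df2 = df2, p_value = pf(f, df1, df2,
                                                 lower.tail = FALSE))
}

#' Multivariate (meta-trait) association by Wilks' lambda
#'
#' Fits the multivariate linear model `Y = X B + E` where the columns of `Y`
#' are the standardized lipid traits (the "meta-lipid" response) and tests
#' the term of interest (`x`, typically a probe's expression) with Wilks'
#' lambda, `Lambda = det(E) / det(E + H)`, where `E` is the residual
#' cross-product matrix of the full model and `H` the extra cross-product
#' attributable to the term (Type III: full vs. the model with the term
#' removed). P values come from Rao's F approximation, exact when the
#' response or hypothesis dimension is at most 2; with a single response
#' column the test reduces to the ordinary univariate F test.
#'
#' @param Y Samples x traits numeric matrix (k >= 1 columns).
#' @param x Predictor of interest (per-sample vector, e.g. probe expression
#'   or SNP dosage).
#' @param covariates Optional tibble of additional regressors.
#' @return An object of class `ll_wilks` with elements `lambda`, `f`,
#'   `df1`, `df2`, `p_value`, `n`, `k`; supports [tidy()] and [glance()].
#' @export
fit_meta_lipids <- function(Y, x, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(length(x) == n)
  C <- .covariate_matrix(covariates, n)
  X_full <- cbind(1, x, C)
  X_red <- cbind(1, C)
  E <- crossprod(qr.resid(qr(X_full), Y))
  E_red <- crossprod(qr.resid(qr(X_red), Y))
  H <- E_red - E
  if (rcond(E) < .Machine$double.eps)
    stop("singular residual covariance", call. = FALSE)
  lambda <- det(E) / det(E + H)
  ve <- n - qr(X_full)$rank
  rao <- .wilks_rao(lambda, p = ncol(Y), h = 1, ve = ve)
  structure(list(lambda = lambda, f = rao$f, df1 = rao$df1, df2 = rao$df2,
                 p_value = rao$p_value, n = n, k = ncol(Y)),
            class = "ll_wilks")
}

#' @export
print.ll_wilks <- function(x, ...) {
  cat(sprintf(
    "Wilks' lambda test (k = %d responses, n = %d)\n  Lambda = %.4f, F(%g, %g) = %.3f, P = %.3g\n",
    x$k, x$n, x$lambda, x$df1, x$df2, x$f, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ll_wilks <- function(x, ...) {
  tibble::tibble(term = "x", wilks_lambda = x$lambda, statistic = x$f,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}

#' @exportS3Method generics::glance
glance.ll_wilks <- function(x, ...) {
  tibble::tibble(wilks_lambda = x$lambda, p_value = x$p_value, n = x$n,
                 k = x$k)
}
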