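#' Standardize a variable to zero mean and unit SD
#'
#' Sample (n-1) SD convention throughout, so z-scores are reproducible
#' bit-for-bit across modules.
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  if (length(unique(x)) < 2) stop("cannot standardize a constant input", call. = FALSE)
  (x - mean(x)) / sd(x)
}

#' Cohen's f-squared from R-squared
#'
#' `f2 = R2 / (1 - R2)`; at the emulated study's lower bound R2 = 0.24 this
#' is 0.316, printing as 0.32.
#'
#' @param r2 coefficient of determination in `[0, 1)`.
#' @return numeric effect size.
#' @export
cohens_f2 <- function(r2) {
  stopifnot(all(r2 >= 0), all(r2 <= 1))
  ifelse(r2 == 1, Inf, r2 / (1 - r2))
}

#' ANCOVA of task scores by lesion side with a lesion-volume covariate
#'
#' Linear model `score ~ side + volume`; the reported F is the type-III
#' (partial) test of side, which for a two-level factor equals the squared
#' t of its coefficient.
#'
#' @param scores numeric task scores.
#' @param side factor/character of lesion sides (two levels, both present).
#' @param volume numeric lesion-volume covariate (total lesion volume in the
#'   emulated design).
#' @return list with `F`, `p`, `df1`, `df2`, `coef` and the fitted `model`.
#' @export
ancova_side <- function(scores, side, volume) {
  side <- as.factor(side)
  if (nlevels(droplevels(side)) != 2)
    stop("both lesion sides must be present", call. = FALSE)
  df <- data.frame(scores = scores, side = side, volume = volume)
  fit <- lm(scores ~ side + volume, data = df)
  if (any(is.na(coef(fit))))
    stop("singular ANCOVA design", call. = FALSE)
  sm <- summary(fit)
  trow <- grep("^side", rownames(sm$coefficients))
  tval <- sm$coefficients[trow, "t value"]
  df2 <- fit$df.residual
  Fval <- tval^2
  list(F = unname(Fval), p = unname(pf(Fval, 1, df2, lower.tail = FALSE)),
       df1 = 1, df2 = df2, coef = coef(fit), model = fit)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Closed form without continuity correction:
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, p from the chi-square
#' distribution with 1 df.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `chi2`, `p`, `df = 1`.
#' @examples
#' chi_square_2x2(matrix(c(13, 24, 72, 94), 2))  # approx 0.844
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: chi-square undefined", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  N <- sum(table)
  chi2 <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = unname(chi2), p = unname(pchisq(chi2, 1, lower.tail = FALSE)), df = 1)
}

#' Multivariate regression of task scores on one tract's lesion load
#'
#' Ordinary least squares of the (standardized) task score on the
#' standardized lesion load with lesion side and standardized grey-matter
#' lesion volume as covariates; per-coefficient two-sided t tests, model R2
#' and Cohen's f2. Setting `gm_volume = NULL` gives the uncontrolled
#' variant without the grey-matter covariate.
#'
#' @param scores numeric response (APM Task Scores).
#' @param load numeric lesion load for one tract family.
#' @param side lesion side, coded or coercible to `{left = 0, right = 1}` so
#'   a positive coefficient means worse scores with right lesions.
#' @param gm_volume grey-matter lesion volume covariate, or `NULL`.
#' @param standardize_response standardize the response too (the emulated
#'   analysis standardizes every variable); set `FALSE` to estimate
#'   coefficients on the response's own scale.
#' @return list of class `tract_regression`: `coef` table (estimate, se, t,
#'   p per predictor), `r2`, `f2`, `n`.
#' @export
tract_regression <- function(scores, load, side, gm_volume = NULL,
                             standardize_response = TRUE) {
  n <- length(scores)
  if (n <= 10) stop("tract regression needs n > 10", call. = FALSE)
  side_num <- if (is.numeric(side)) side else as.numeric(side == "right")
  y <- if (standardize_response) standardize(scores) else scores
  Xp <- cbind(load = standardize(load), side = standardize(side_num))
  if (!is.null(gm_volume)) Xp <- cbind(Xp, gm_volume = standardize(gm_volume))
  X <- cbind(`(Intercept)` = 1, Xp)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: predictors are collinear", call. = FALSE)
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXi))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(
    coef = data.frame(term = colnames(X), estimate = beta, se = se,
                      t = tval, p = pval, row.names = NULL),
    r2 = r2, f2 = cohens_f2(r2), n = n, df = df
  ), class = "tract_regression")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up rule at level `q`: reject all hypotheses with p at or below
#' `p_(k*)` where `k* = max{k : p_(k) <= k q / m}`. Adjusted p-values are the
#' standard monotone BH adjustment; rejection is `p_adjusted <= q`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `reject` (logical), `p_adjusted`, `q`, `m`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, q = q, m = length(p))
}

#' Tract-wise regression battery with pooled FDR correction
#'
#' Applies the inclusion filter, runs one [tract_regression()] per included
#' tract family (single per-family load predictor via [family_loads()]), and
#' pools all non-intercept coefficient tests into one FDR family (3
#' coefficients x 23 tracts = 69 tests on the emulated design) corrected at
#' `q` by Benjamini-Hochberg.
#'
#' @param scores numeric task scores.
#' @param loads data frame with `<family>_left` / `<family>_right` columns.
#' @param side lesion sides.
#' @param gm_volume grey-matter lesion volumes (or `NULL` for the
#'   uncontrolled variant).
#' @param min_n inclusion filter bound (strict, default 25).
#' @param q FDR level.
#' @return list of class `tract_battery`: `included` families, `fits`
#'   (per-family [tract_regression()]s), `tests` (pooled long table with
#'   adjusted p and rejection flags), `q`.
#' @export
tract_regression_battery <- function(scores, loads, side, gm_volume,
                                     min_n = 25, q = 0.05) {
  included <- tract_inclusion_filter(loads, min_n = min_n)
  if (!length(included))
    stop("no tract family passes the inclusion filter", call. = FALSE)
  fl <- family_loads(loads, included)
  fits <- lapply(included, function(f)
    tract_regression(scores, fl[[f]], side, gm_volume))
  names(fits) <- included
  tests <- do.call(rbind, lapply(included, function(f) {
    ct <- fits[[f]]$coef
    ct <- ct[ct$term != "(Intercept)", ]
    cbind(tract = f, ct)
  }))
  fdr <- bh_fdr(tests$p, q)
  tests$p_adjusted <- fdr$p_adjusted
  tests$significant <- fdr$reject
  structure(list(included = included, fits = fits, tests = tests, q = q),
            class = "tract_battery")
}

#' Principal component analysis of the standardized predictor table
#'
#' Eigendecomposition of the correlation matrix of the predictors (the 23
#' tract-family loads plus grey-matter lesion volume in the emulated
#' design: 24 columns). Components are ordered by eigenvalue; the selected
#' count is the smallest k whose cumulative explained variance reaches
#' `var_target` (95% by default).
#'
#' @param predictors numeric data frame / matrix of predictors (no constant
#'   columns).
#' @param var_target cumulative-variance selection target in percent.
#' @return list of class `pca_predictors`: `loadings` (predictor x
#'   component), `eigenvalues`, `pct_variance`, `cum_variance`, `selected`
#'   (component count), `scores` (observation x component).
#' @export
pca_predictors <- function(predictors, var_target = 95) {
  X <- as.matrix(predictors)
  if (any(apply(X, 2, function(c) length(unique(c)) < 2)))
    stop("degenerate predictor: constant column", call. = FALSE)
  Xs <- apply(X, 2, standardize)
  C <- stats::cor(Xs)
  eg <- eigen(C, symmetric = TRUE)
  eigenvalues <- pmax(eg$values, 0)
  pct <- 100 * eigenvalues / sum(eigenvalues)
  cum <- cumsum(pct)
  selected <- which(cum >= var_target)[1]
  loadings <- eg$vectors
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncol(loadings))))
  scores <- Xs %*% loadings
  structure(list(loadings = loadings, eigenvalues = eigenvalues,
                 pct_variance = pct, cum_variance = cum, selected = selected,
                 scores = scores, var_target = var_target),
            class = "pca_predictors")
}

#' @export
print.pca_predictors <- function(x, ...) {
  cat(sprintf("<pca_predictors> %d predictors; %d components reach %.0f%% variance (%.1f%%)\n",
              nrow(x$loadings), x$selected, x$var_target,
              x$cum_variance[x$selected]))
  invisible(x)
}

#' Principal component regression of task scores
#'
#' OLS of the (standardized) task score on the selected principal-component
#' scores, with two-sided t tests per component and BH-FDR over those k
#' tests.
#'
#' @param pca a [pca_predictors()] result.
#' @param scores numeric task scores.
#' @param k number of components (default: the 95%-variance selection).
#' @param q FDR level over the k component tests.
#' @param standardize_response standardize the response before fitting.
#' @return list of class `pc_regression`: `coef` table (per component:
#'   estimate, se, t, p, adjusted p, significance), `r2`, `f2`, `k`.
#' @export
pc_regression <- function(pca, scores, k = pca$selected, q = 0.05,
                          standardize_response = TRUE) {
  stopifnot(inherits(pca, "pca_predictors"), k >= 1)
  y <- if (standardize_response) standardize(scores) else scores
  S <- pca$scores[, seq_len(k), drop = FALSE]
  X <- cbind(`(Intercept)` = 1, S)
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXi))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  ct <- data.frame(term = colnames(X), estimate = beta, se = se, t = tval,
                   p = pval, row.names = NULL)
  comp <- ct$term != "(Intercept)"
  fdr <- bh_fdr(ct$p[comp], q)
  ct$p_adjusted <- NA_real_; ct$significant <- NA
  ct$p_adjusted[comp] <- fdr$p_adjusted
  ct$significant[comp] <- fdr$reject
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(coef = ct, r2 = r2, f2 = cohens_f2(r2), k = k, q = q),
            class = "pc_regression")
}
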