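test_that("standardize uses the sample-SD convention and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(61)
  x <- rnorm(200, 5, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("Cohen's f2 follows its identity and matches the printed rounding", {
  r2 <- seq(0, 0.9, by = 0.1)
  expect_equal(cohens_f2(r2), r2 / (1 - r2), tolerance = 1e-12)
  expect_true(all(diff(cohens_f2(r2)) > 0))
  expect_equal(round(cohens_f2(0.24), 2), 0.32)
  expect_equal(round(cohens_f2(0.31), 2), 0.45)  # upper bound of the range
})

test_that("the side ANCOVA equals a from-scratch projection oracle", {
  set.seed(62)
  n <- 80
  side <- rep(c("left", "right"), n / 2)
  vol <- rlnorm(n, 3, 0.8)
  y <- 1 + 0.5 * (side == "right") + 0.02 * vol + rnorm(n)
  res <- ancova_side(y, side, vol)

  # oracle: F from residual sums of squares of nested hat matrices
  X1 <- cbind(1, vol)
  X2 <- cbind(1, vol, side == "right")
  rss <- function(X) { H <- X %*% solve(crossprod(X)) %*% t(X); sum(((diag(n) - H) %*% y)^2) }
  F_oracle <- (rss(X1) - rss(X2)) / (rss(X2) / (n - 3))
  expect_equal(res$F, F_oracle, tolerance = 1e-8)
  expect_equal(res$p, pf(F_oracle, 1, n - 3, lower.tail = FALSE), tolerance = 1e-8)

  # equal group means, covariate unrelated to side: F stays small
  res0 <- ancova_side(1 + 0.001 * rnorm(n), side, vol)
  expect_lt(res0$F, 4)
  expect_error(ancova_side(y, rep("left", n), vol), "both lesion sides")
})

test_that("chi-square matches the closed form, the reconstruction, and chisq.test", {
  res <- chi_square_2x2(rbind(c(13, 72), c(24, 94)))
  expect_equal(res$chi2, 0.844, tolerance = 5e-4)
  expect_equal(res$p, 0.358, tolerance = 5e-3)
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  expect_equal(chi_square_2x2(rbind(c(20, 0), c(0, 20)))$chi2, 40)
  set.seed(63)
  tab <- matrix(rpois(4, 30) + 1, 2)
  expect_equal(chi_square_2x2(tab)$chi2,
               unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_error(chi_square_2x2(rbind(c(1.5, 2), c(3, 4))), "integers")
})

test_that("tract regression interpolates noise-free data and reports f2", {
  set.seed(64)
  n <- 50
  load <- runif(n, 0, 80); side <- rbinom(n, 1, 0.5); gm <- rlnorm(n, 2, 0.7)
  y <- 2 + 0.7 * standardize(load) - 0.3 * standardize(side) +
    0.4 * standardize(gm)
  fit <- tract_regression(y, load, side, gm, standardize_response = FALSE)
  est <- setNames(fit$coef$estimate, fit$coef$term)
  expect_equal(est[["load"]], 0.7, tolerance = 1e-8)
  expect_equal(est[["side"]], -0.3, tolerance = 1e-8)
  expect_equal(est[["gm_volume"]], 0.4, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  yn <- y + rnorm(n)
  fit2 <- tract_regression(yn, load, side, gm)
  expect_equal(fit2$f2, fit2$r2 / (1 - fit2$r2), tolerance = 1e-12)
  # against lm() as an independent route
  ref <- summary(lm(standardize(yn) ~ standardize(load) + standardize(side) +
                      standardize(gm)))
  expect_equal(fit2$coef$p[-1], unname(ref$coefficients[-1, "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_error(tract_regression(yn, load, side, load), "collinear")
  expect_error(tract_regression(yn[1:5], load[1:5], side[1:5], gm[1:5]),
               "n > 10")
})

test_that("BH-FDR reproduces hand-computed step-up decisions", {
  res <- bh_fdr(c(0.001, 0.01, 0.03, 0.2), q = 0.05)
  expect_identical(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$p_adjusted, c(0.004, 0.02, 0.04, 0.2), tolerance = 1e-12)
  expect_identical(bh_fdr(rep(1, 10))$reject, rep(FALSE, 10))
  expect_identical(bh_fdr(0.04)$reject, TRUE)
  # adjusted p is monotone in p
  set.seed(65)
  p <- sort(runif(30))
  expect_true(all(diff(bh_fdr(p)$p_adjusted) >= 0))
})

test_that("BH on independent null p-values controls the FDR level", {
  set.seed(66)
  any_false <- vapply(1:400, function(i)
    any(bh_fdr(runif(20))$reject), logical(1))
  expect_lte(mean(any_false), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("PCA eigenstructure matches analytic cases and reconstructs", {
  set.seed(67)
  n <- 4000
  X <- matrix(rnorm(n * 6), n, 6)
  p1 <- pca_predictors(X)
  expect_true(all(abs(p1$eigenvalues - 1) < 0.15))       # independent cols
  expect_true(all(diff(p1$eigenvalues) <= 1e-12))        # non-increasing
  expect_equal(sum(p1$pct_variance), 100, tolerance = 1e-9)

  # duplicated predictor among independents: top eigenvalue ~ 2
  X2 <- cbind(X, X[, 1] + rnorm(n, 0, 1e-6))
  p2 <- pca_predictors(X2)
  expect_equal(p2$eigenvalues[1], 2, tolerance = 0.1)

  # retaining all components reconstructs the standardized table
  Xs <- apply(X[1:200, ], 2, standardize)
  p3 <- pca_predictors(X[1:200, ])
  expect_equal(p3$scores[1:200, ] %*% t(p3$loadings), Xs,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_predictors(cbind(X, 0)), "constant")
})

test_that("PC regression respects orthogonality identities", {
  set.seed(68)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  pca <- pca_predictors(X, var_target = 100)
  # response built along component 1 only
  y1 <- pca$scores[, 1] * 0.8 + rnorm(n, 0, 0.3)
  fit <- pc_regression(pca, y1, k = 5, standardize_response = FALSE)
  sig <- fit$coef$significant[-1]
  expect_true(sig[1])
  expect_false(any(sig[-1]))

  # coefficient identity: beta_j = cov(y, score_j) / eigenvalue_j
  y <- rnorm(n) + X %*% runif(5)
  fit2 <- pc_regression(pca, y, k = 5, standardize_response = FALSE)
  for (j in 1:5) {
    expect_equal(fit2$coef$estimate[j + 1],
                 cov(as.numeric(y), pca$scores[, j]) / pca$eigenvalues[j],
                 tolerance = 1e-8)
  }
})

test_that("null regressions give uniform p-values", {
  set.seed(69)
  n <- 60
  load <- runif(n, 0, 60); side <- rbinom(n, 1, 0.5); gm <- rlnorm(n, 2, 0.6)
  p <- vapply(1:500, function(i) {
    fit <- tract_regression(rnorm(n), load, side, gm)
    fit$coef$p[fit$coef$term == "load"]
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})
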