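test_that("mirroring reflects x about the midline and is an involution", {
  expect_equal(mirror_match(c(5, 10)), c(-5, 10))
  expect_equal(mirror_match(c(0, 7)), c(0, 7))
  expect_equal(mirror_match(mirror_match(c(3.2, -4))), c(3.2, -4))
  expect_equal(mirror_match(c(5, 10), midline_x = 2), c(-1, 10))
  m <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(mirror_match(m), cbind(-m[, 1], m[, 2]))
})

test_that("matching parameters recover constructed phenotypes exactly", {
  # perfect mirrored matching
  p0 <- compute_matching_parameters(perfect_session())
  expect_equal(p0$abs_error_xy, 0)
  expect_equal(p0$variability_xy, 0)
  expect_equal(p0$shift_x, 0)
  expect_equal(p0$shift_y, 0)
  expect_equal(p0$ratio_x, 1)
  expect_equal(p0$ratio_y, 1)

  # uniform +20 mm x offset after mirroring: x errors 20, y errors 0
  ps <- compute_matching_parameters(
    perfect_session(function(m) { m[, 1] <- m[, 1] + 20; m }))
  expect_equal(ps$shift_x, 20)
  expect_equal(ps$abs_error_xy, 10)   # pooled over x and y
  expect_equal(ps$variability_xy, 0)
  expect_equal(ps$ratio_x, 1)

  # scaling by 0.5 about the workspace centroid: contraction phenotype
  ctr <- colMeans(apm_targets())
  pc <- compute_matching_parameters(
    perfect_session(function(m) sweep(sweep(m, 2, ctr) * 0.5, 2, ctr, "+")))
  expect_equal(pc$ratio_x, 0.5)
  expect_equal(pc$ratio_y, 0.5)
})

test_that("incomplete sessions are rejected", {
  s <- perfect_session()
  expect_error(compute_matching_parameters(s[-1, ]), "incomplete")
  s2 <- s
  s2$target[1] <- 2   # duplicate target within block 1
  expect_error(compute_matching_parameters(s2), "once per block")
})

test_that("the zeta transform matches its closed form and inverts cleanly", {
  expect_equal(zeta_transform(0), qnorm(0.75), tolerance = 1e-10)
  expect_equal(zeta_transform(0), 0.6745, tolerance = 1e-4)
  expect_equal(zeta_transform(1.96), 2.2414, tolerance = 1e-4)
  expect_lt(zeta_transform(-8), 1e-8)         # best performance -> ~0
  z <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(zeta_transform(z)) > 0))
  # bijection on the zeta scale: zeta(zeta^-1(x)) = x within 1e-10
  x <- seq(0.001, 8, by = 0.2)
  expect_lt(max(abs(zeta_transform(zeta_inverse(x)) - x)), 1e-10)
  zz <- seq(-3, 6, by = 0.25)
  expect_lt(max(abs(zeta_inverse(zeta_transform(zz)) - zz)), 1e-8)
  expect_true(is.finite(zeta_transform(100)))  # no overflow in the far tail
})

test_that("normative fit recovers injected covariate effects and standardizes", {
  fix <- small_normative()
  model <- fix$model
  cohort <- fix$cohort

  # batch z-scores of the fitting cohort are standard
  P <- t(vapply(cohort$session, function(s)
    unlist(compute_matching_parameters(s)), numeric(6)))
  colnames(P) <- apm_parameter_names <- propriomap:::apm_parameter_names()
  for (p in c("abs_error_xy", "variability_xy", "shift_x")) {
    z <- vapply(seq_len(nrow(cohort)), function(i)
      zscore_parameter(model, p, P[i, p], cohort[i, ]), numeric(1))
    expect_lt(abs(mean(z)), 0.05)
    expect_lt(abs(sd(z) - 1), 0.05)
  }

  # the generator's age slope on (log) variability is recovered within 2 SE:
  # oracle refit of the same regression gives the SE
  big <- make_normative_cohort(500, n_controls = 250, n_assessments = 300)
  m2 <- normative_fit(big)
  vb <- vapply(big$session, function(s)
    compute_matching_parameters(s)$variability_xy, numeric(1))
  oracle <- summary(lm(log(vb) ~ age + sex + handedness, data = big))
  slope_true <- 0.02 / 5   # d log(noise)/d age at the 5 mm baseline
  expect_lt(abs(m2$coefs["age", "variability_xy"] - slope_true),
            2 * oracle$coefficients["age", "Std. Error"])
  expect_equal(m2$coefs["age", "variability_xy"],
               unname(oracle$coefficients["age", "Estimate"]), tolerance = 1e-8)
})

test_that("z-scores sit where the model predicts", {
  model <- small_normative()$model
  cov <- list(age = 60, sex = 1, handedness = 1)
  x <- c(1, cov$age, cov$sex, cov$handedness)
  pred <- drop(x %*% model$coefs[, "shift_x"])
  expect_equal(zscore_parameter(model, "shift_x", pred, cov), 0)
  expect_equal(zscore_parameter(model, "shift_x",
                                pred + model$sigma[["shift_x"]], cov), 1)
  predv <- exp(drop(x %*% model$coefs[, "variability_xy"]))
  expect_equal(zscore_parameter(model, "variability_xy", predv, cov), 0)
  expect_error(zscore_parameter(model, "variability_xy", -1, cov), "positive")
})

test_that("normative fit enforces its preconditions", {
  fix <- small_normative()$cohort
  expect_error(normative_fit(fix[1:10, ]), ">= 30")
  onesex <- fix; onesex$sex <- 1
  expect_error(normative_fit(onesex), "both sexes")
  const <- fix; const$age <- 60
  expect_error(normative_fit(const), "constant")
})

test_that("task scores classify impairment at the 1.96 cut and rank monotonically", {
  model <- small_normative()$model
  tm <- ground_truth()$trial_model
  cov <- list(age = 60, sex = 1, handedness = 1)
  set.seed(31)
  hi <- task_score(propriomap:::simulate_session(3, 60, 1, 1, tm), cov, model)
  lo <- task_score(propriomap:::simulate_session(0, 60, 1, 1, tm), cov, model)
  expect_true(hi$task_score > 1.96 && hi$impaired)
  expect_false(lo$impaired)
  expect_gte(hi$task_score, 0)

  # the RSS -> score map is monotone, and the normative median lands at zeta(0)
  rss_grid <- seq(0.5, 12, by = 0.25)
  sc <- zeta_transform(propriomap:::rank_inverse_normal(rss_grid, model$rss_sample))
  expect_true(all(diff(sc) >= 0))
  med <- median(model$rss_sample)
  expect_equal(
    zeta_transform(propriomap:::rank_inverse_normal(med, model$rss_sample)),
    zeta_transform(0), tolerance = 0.05)
})

test_that("scoring is scale-consistent under a unit change with refit", {
  set.seed(32)
  cohort <- make_normative_cohort(403, n_controls = 40, n_assessments = 50)
  m1 <- normative_fit(cohort)
  scale2 <- function(s) { s[c("robot_x", "robot_y", "match_x", "match_y")] <-
    s[c("robot_x", "robot_y", "match_x", "match_y")] * 2; s }
  cohort2 <- cohort
  cohort2$session <- lapply(cohort$session, scale2)
  m2 <- normative_fit(cohort2)
  tm <- ground_truth()$trial_model
  set.seed(33)
  s <- propriomap:::simulate_session(1.5, 55, 0, 1, tm)
  cov <- list(age = 55, sex = 0, handedness = 1)
  t1 <- task_score(s, cov, m1)
  t2 <- task_score(scale2(s), cov, m2)
  expect_equal(t1$z, t2$z, tolerance = 1e-8)
  expect_equal(t1$task_score, t2$task_score, tolerance = 1e-8)
})
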