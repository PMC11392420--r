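test_that("cohort generators are deterministic under a fixed seed", {
  a <- make_normative_cohort(90, n_controls = 10, n_assessments = 12)
  b <- make_normative_cohort(90, n_controls = 10, n_assessments = 12)
  expect_identical(a, b)
  br <- tiny_brain()
  c1 <- make_stroke_cohort(91, br, ground_truth(causal_tracts = c(tract1 = 0.5)),
                           n = 6)
  c2 <- make_stroke_cohort(91, br, ground_truth(causal_tracts = c(tract1 = 0.5)),
                           n = 6)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$sessions, c2$sessions)
})

test_that("a zeroed trial model at severity zero matches targets perfectly", {
  tm <- list(shift_per_sd = 10, contraction_per_sd = 0.1, contraction_floor = 0.2,
             noise_base = 0, noise_per_sd = 0, noise_floor = 0,
             subject_shift_sd = 0, subject_contraction_sd = 0,
             subject_lognoise_sd = 0)
  eff <- list(age_noise = 0, sex_noise = 0, hand_shift = 0)
  s <- propriomap:::simulate_session(0, 60, 1, 1, tm, eff)
  expect_equal(s$match_x, -s$robot_x, tolerance = 1e-12)
  expect_equal(s$match_y, s$robot_y, tolerance = 1e-12)
  p <- compute_matching_parameters(s)
  expect_equal(p$abs_error_xy, 0)
  expect_equal(p$ratio_x, 1)
})

test_that("sessions respect the 54-trial block design", {
  cohort <- make_normative_cohort(92, n_controls = 5, n_assessments = 6)
  for (s in cohort$session) {
    expect_equal(nrow(s), 54)
    expect_true(all(table(s$target, s$block) == 1))
  }
  expect_error(make_normative_cohort(93, n_controls = 10, n_assessments = 5),
               "n_assessments")
})

test_that("a fully null truth yields constant latent scores at the intercept", {
  br <- tiny_brain()
  tr <- ground_truth(causal_tracts = numeric(0), side_effect = 0, gm_effect = 0,
                     noise_sd = 0, intercept = 0.4)
  co <- make_stroke_cohort(94, br, tr, n = 5)
  expect_equal(co$table$latent, rep(0.4, 5), tolerance = 1e-12)
})

test_that("the latent model composes effects as specified", {
  br <- tiny_brain()
  tr <- ground_truth(causal_tracts = c(tract2 = 0.6), side_effect = 0.3,
                     gm_effect = 0.2, noise_sd = 0, intercept = 1)
  co <- make_stroke_cohort(95, br, tr, n = 40)
  tab <- co$table
  zstd <- function(x) (x - mean(x)) / sd(x)
  expected <- 1 + 0.3 * (tab$side == "right") + 0.6 * zstd(tab$tract2) +
    0.2 * zstd(tab$gm_lesion_cc)
  expect_equal(tab$latent, expected, tolerance = 1e-10)
})

test_that("side composition and lesion laterality follow the configuration", {
  br <- tiny_brain()
  co <- make_stroke_cohort(96, br, null_ground_truth(), n = 12, p_right = 1)
  expect_true(all(co$table$side == "right"))
  gw <- propriomap:::grid_world_coords(br$grid)
  for (les in co$lesions[1:3])
    expect_equal(sum(les$values[gw$xyz[, 1] < 0]), 0)
  expect_error(make_stroke_cohort(97, br, ground_truth(c(nope = 1)), n = 5),
               "not in brain atlas")
})

test_that("emulated cohort sizes are accepted and volumes follow the target law", {
  # the full normative design (2227 assessments / 799 controls) is accepted
  # by the argument contract; exercised at reduced size for speed
  expect_silent(ok <- make_normative_cohort(98, n_controls = 799,
                                            n_assessments = 799 + 1)[0, ])
  br <- tiny_brain()
  co <- make_stroke_cohort(99, br, null_ground_truth(), n = 60)
  # targets are clamped to [1, 80] cc; achieved volumes are exact to the voxel
  expect_true(all(co$table$total_lesion_cc >= 0.9 &
                  co$table$total_lesion_cc <= 81))
  expect_true(is.logical(co$table$ipsi_impaired))
})
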