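#' Ground-truth generative model for synthetic cohorts
#'
#' Encodes the causal structure the cohort statistics assume: a latent
#' severity score built additively from standardized tract lesion loads,
#' lesion side and grey-matter lesion volume, plus Gaussian noise, and a
#' trial model mapping severity to the three observable matching phenotypes
#' (systematic shift, workspace contraction, trial-to-trial variability).
#'
#' Severity is expressed in normative-SD units: a participant at severity 1
#' performs about one control-SD worse than a typical control. The trial
#' model defaults map severity `s` to a `10*s` mm rightward shift, a
#' contraction factor `max(0.2, 1 - 0.1*s)` and a per-coordinate trial noise
#' SD of `max(0.5, 5 + 3*s)` mm, reproducing the canonical variability /
#' contraction / shift phenotypes with a single knob.
#'
#' @param causal_tracts named numeric vector: effect (severity units per SD
#'   of lesion load) per tract *family* name (e.g. `"tract1"`). May be empty
#'   for a null cohort.
#' @param side_effect additive effect of a right-hemisphere lesion.
#' @param gm_effect effect per SD of grey-matter lesion volume.
#' @param noise_sd SD of the latent noise (>= 0).
#' @param intercept baseline severity of a lesioned participant.
#' @param trial_model list of trial-model knobs: `shift_per_sd` (mm),
#'   `contraction_per_sd`, `contraction_floor`, `noise_base` (mm),
#'   `noise_per_sd` (mm), `noise_floor` (mm), plus the between-subject
#'   baseline variation every real cohort shows even at severity zero:
#'   `subject_shift_sd` (mm, idiosyncratic x/y shift), `subject_contraction_sd`
#'   (idiosyncratic workspace scaling) and `subject_lognoise_sd` (log-scale
#'   spread of individual trial noise).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(causal_tracts = c(tract1 = 0.5, tract2 = 0.5),
                         side_effect = 0.3, gm_effect = 0.2,
                         noise_sd = 1, intercept = 0.8,
                         trial_model = list(shift_per_sd = 10,
                                            contraction_per_sd = 0.1,
                                            contraction_floor = 0.2,
                                            noise_base = 5,
                                            noise_per_sd = 3,
                                            noise_floor = 0.5,
                                            subject_shift_sd = 3,
                                            subject_contraction_sd = 0.05,
                                            subject_lognoise_sd = 0.15)) {
  stopifnot(noise_sd >= 0, trial_model$contraction_floor > 0)
  if (length(causal_tracts) && is.null(names(causal_tracts)))
    stop("`causal_tracts` must be named by tract family", call. = FALSE)
  structure(list(causal_tracts = causal_tracts, side_effect = side_effect,
                 gm_effect = gm_effect, noise_sd = noise_sd,
                 intercept = intercept, trial_model = trial_model),
            class = "ground_truth")
}

#' A ground truth with every effect switched off
#'
#' Null cohorts drawn under this truth feed the type-I-error calibration of
#' the regression and voxelwise inference suites.
#'
#' @param noise_sd latent noise SD.
#' @return a [ground_truth()] with all beta = 0 and intercept 0.
#' @export
null_ground_truth <- function(noise_sd = 1) {
  ground_truth(causal_tracts = numeric(0), side_effect = 0, gm_effect = 0,
               noise_sd = noise_sd, intercept = 0)
}

# Default mild covariate effects in the normative generator: trial noise
# grows slowly with age and differs slightly by sex; handedness nudges the
# systematic shift. All effects stay well under 0.3 SD over the covariate
# range so z-scoring matters without dominating.
default_normative_effects <- function() {
  list(age_noise = 0.02,    # mm of trial-noise SD per year beyond age 50
       sex_noise = 0.3,     # mm of trial-noise SD for sex == 1
       hand_shift = 0.5)    # mm of x shift per handedness unit
}

# Simulate one 54-trial session at a given latent severity.
simulate_session <- function(severity, age, sex, handedness,
                             trial_model, effects = default_normative_effects(),
                             targets = apm_targets(), n_blocks = 6L) {
  tm <- trial_model
  subj_sh <- tm$subject_shift_sd %||% 0
  subj_co <- tm$subject_contraction_sd %||% 0
  subj_no <- tm$subject_lognoise_sd %||% 0
  shift_x <- tm$shift_per_sd * severity + effects$hand_shift * handedness +
    rnorm(1, 0, subj_sh)
  shift_y <- rnorm(1, 0, subj_sh)
  contraction <- max(tm$contraction_floor,
                     1 - tm$contraction_per_sd * severity + rnorm(1, 0, subj_co))
  noise_sd <- max(tm$noise_floor,
                  (tm$noise_base + tm$noise_per_sd * severity +
                     effects$age_noise * (age - 50) + effects$sex_noise * sex) *
                    exp(rnorm(1, 0, subj_no)))
  centroid <- colMeans(targets)
  n_targets <- nrow(targets)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    ord <- sample.int(n_targets)
    rob <- targets[ord, , drop = FALSE]
    mirr <- sweep(sweep(rob, 2, centroid) * contraction, 2, centroid, "+")
    mirr[, 1] <- mirr[, 1] + shift_x
    mirr[, 2] <- mirr[, 2] + shift_y
    mirr <- mirr + matrix(rnorm(2L * n_targets, 0, noise_sd), ncol = 2)
    rows[[b]] <- data.frame(target = ord, block = b,
                            robot_x = rob[, 1], robot_y = rob[, 2],
                            match_x = -mirr[, 1], match_y = mirr[, 2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a normative (control) cohort
#'
#' Draws control participants (age, sex, handedness) and their matching
#' sessions at severity zero, with the mild covariate effects of
#' `effects` so that covariate adjustment in the normative fit is exercised.
#' The emulated study design uses 2227 assessments from 799 controls
#' (controls may contribute several assessments).
#'
#' @param seed integer RNG seed.
#' @param n_controls number of distinct control participants.
#' @param n_assessments total assessments (>= `n_controls`).
#' @param effects covariate-effect knobs, see `default_normative_effects()`.
#' @param trial_model trial-model knobs (see [ground_truth()]); severity is 0.
#' @return data frame with `assessment_id`, `control_id`, `age`, `sex`,
#'   `handedness` and a `session` list-column of trial data frames.
#' @export
make_normative_cohort <- function(seed, n_controls = 799, n_assessments = 2227,
                                  effects = default_normative_effects(),
                                  trial_model = ground_truth()$trial_model) {
  stopifnot(n_assessments >= n_controls, n_controls >= 2)
  with_seed(seed, {
    age <- round(runif(n_controls, 18, 85))
    sex <- rbinom(n_controls, 1, 0.5)
    handedness <- sample(c(1, -1), n_controls, replace = TRUE, prob = c(0.9, 0.1))
    who <- c(seq_len(n_controls),
             sample.int(n_controls, n_assessments - n_controls, replace = TRUE))
    cohort <- data.frame(assessment_id = seq_len(n_assessments),
                         control_id = who,
                         age = age[who], sex = sex[who],
                         handedness = handedness[who])
    cohort$session <- lapply(seq_len(n_assessments), function(i)
      simulate_session(0, cohort$age[i], cohort$sex[i], cohort$handedness[i],
                       trial_model, effects))
    cohort
  })
}

#' Generate a stroke cohort with known ground truth
#'
#' For each participant: a lesion side (right with probability `p_right`,
#' default the emulated 118:85 split), a lesion volume drawn from a
#' log-normal matched to the emulated 30.5 +- 39.3 cc distribution, a
#' synthetic lesion mask, tract lesion loads and grey-matter lesion volume,
#' a latent severity
#' `intercept + side_effect*right + sum(beta_t * std(load_t)) + gm_effect*std(gm) + noise`,
#' and a 54-trial matching session generated at that severity. All
#' ground-truth quantities are stored for recovery tests. An independent
#' binary ipsilesional-motor-impairment flag (base rate `p_ipsi`) is stored
#' for the side-association test.
#'
#' @param seed integer RNG seed.
#' @param brain a [make_brain()] result.
#' @param truth a [ground_truth()].
#' @param n cohort size (>= 2; the emulated study has 203).
#' @param p_right probability of a right-hemisphere lesion.
#' @param p_ipsi base rate of the ipsilesional-impairment flag.
#' @param volume_meanlog,volume_sdlog log-normal lesion-volume parameters
#'   (defaults match mean 30.5, SD 39.3 cc).
#' @param volume_range admissible volume range (cc); draws are clamped.
#' @param effects normative covariate-effect knobs (shared with the control
#'   generator so scoring stays calibrated).
#' @return an object of class `stroke_cohort`: list with `table`
#'   (participant covariates, side, volumes, per-map loads, family loads,
#'   latent severity), `lesions` (list of masks), `sessions` (list of trial
#'   data frames), `truth`, and `brain`.
#' @export
make_stroke_cohort <- function(seed, brain, truth = ground_truth(), n = 203,
                               p_right = 118 / 203, p_ipsi = 0.18,
                               volume_meanlog = log(30.5) - 0.489,
                               volume_sdlog = 0.989,
                               volume_range = c(1, 80),
                               effects = default_normative_effects()) {
  stopifnot(inherits(brain, "synthetic_brain"), inherits(truth, "ground_truth"),
            n >= 2)
  fam_names <- unique(sub("_(left|right)$", "", names(brain$tract_maps)))
  unknown <- setdiff(names(truth$causal_tracts), fam_names)
  if (length(unknown))
    stop("causal tracts not in brain atlas: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  with_seed(seed, {
    age <- pmin(95, pmax(18, round(rnorm(n, 62.2, 14.4))))
    sex <- rbinom(n, 1, 128 / 203)
    handedness <- sample(c(1, -1), n, replace = TRUE, prob = c(0.9, 0.1))
    side <- ifelse(runif(n) < p_right, "right", "left")
    vol <- pmin(volume_range[2], pmax(volume_range[1],
                                      rlnorm(n, volume_meanlog, volume_sdlog)))
    ipsi_impaired <- rbinom(n, 1, p_ipsi) == 1

    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lesions <- lapply(seq_len(n), function(i)
      make_lesion(sub_seeds[i], brain, side[i], vol[i]))

    load_tab <- tract_load_table(lesions, brain$tract_maps, brain$gm_mask)
    loads <- as.matrix(load_tab[, names(brain$tract_maps), drop = FALSE])
    gm_cc <- load_tab$gm_lesion_cc
    total_cc <- load_tab$total_lesion_cc

    fam_load <- vapply(fam_names, function(f)
      pmax(loads[, paste0(f, "_left")], loads[, paste0(f, "_right")]),
      numeric(n))

    zstd <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
    latent <- truth$intercept + truth$side_effect * (side == "right") +
      truth$gm_effect * zstd(gm_cc)
    for (f in names(truth$causal_tracts))
      latent <- latent + truth$causal_tracts[[f]] * zstd(fam_load[, f])
    latent <- latent + rnorm(n, 0, truth$noise_sd)

    sessions <- lapply(seq_len(n), function(i)
      simulate_session(latent[i], age[i], sex[i], handedness[i],
                       truth$trial_model, effects))

    tab <- data.frame(participant_id = seq_len(n), age = age, sex = sex,
                      handedness = handedness, side = side,
                      total_lesion_cc = total_cc, gm_lesion_cc = gm_cc,
                      ipsi_impaired = ipsi_impaired, latent = latent)
    tab <- cbind(tab, as.data.frame(loads), as.data.frame(fam_load))

    structure(list(table = tab, lesions = lesions, sessions = sessions,
                   truth = truth, brain = brain,
                   fam_names = fam_names, map_names = names(brain$tract_maps)),
              class = "stroke_cohort")
  })
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(sprintf("<stroke_cohort> n = %d (%d right / %d left lesions); %d tract families\n",
              nrow(x$table), sum(x$table$side == "right"),
              sum(x$table$side == "left"), length(x$fam_names)))
  invisible(x)
}

#' Attach covariates + sessions of a stroke cohort as a scoring table
#'
#' Convenience reshaping so [score_cohort()] applies directly.
#'
#' @param cohort a [make_stroke_cohort()] result.
#' @return data frame with covariates and a `session` list-column.
#' @export
cohort_sessions <- function(cohort) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  out <- cohort$table[, c("participant_id", "age", "sex", "handedness")]
  out$session <- cohort$sessions
  out
}
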