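#' Arm position matching: task design and parameter extraction
#'
#' The robotic task moves the stroke-affected arm to one of nine targets
#' (a 3 x 3 square, eight outer targets around a centre target) and the
#' participant mirror-matches with the opposite arm, without vision. Each
#' target is tested once per block over six blocks: 54 trials per session.
#'
#' @name apm-task
NULL

#' Nine-target layout of the matching task
#'
#' Target positions (mm) in the affected-arm frame of a body-centred
#' coordinate system whose midline is x = 0. The matching arm's workspace is
#' the mirror image across that midline.
#'
#' @param centre_x,centre_y workspace centre (mm).
#' @param spacing centre-to-centre target spacing (mm).
#' @return 9 x 2 matrix of target x/y (rows = target index 1..9).
#' @export
apm_targets <- function(centre_x = 180, centre_y = 150, spacing = 100) {
  g <- expand.grid(x = centre_x + spacing * (-1:1),
                   y = centre_y + spacing * (-1:1))
  m <- as.matrix(g)
  rownames(m) <- NULL
  m
}

#' Reflect a matched hand position across the body midline
#'
#' The matching arm works in the mirror-image workspace; reflecting its x
#' coordinate across the midline makes matched and robot positions directly
#' comparable. y is unchanged. The reflection is an involution.
#'
#' @param match_xy numeric length-2 vector or n x 2 matrix of positions (mm).
#' @param midline_x x coordinate of the midline (mm); default 0.
#' @return positions of the same shape, x reflected.
#' @examples
#' mirror_match(c(5, 10))       # -> (-5, 10)
#' @export
mirror_match <- function(match_xy, midline_x = 0) {
  if (is.null(dim(match_xy))) {
    c(2 * midline_x - match_xy[1], match_xy[2])
  } else {
    cbind(2 * midline_x - match_xy[, 1], match_xy[, 2])
  }
}

validate_session <- function(trials, n_targets = 9L, n_blocks = 6L) {
  need <- c("target", "block", "robot_x", "robot_y", "match_x", "match_y")
  if (!all(need %in% names(trials)))
    stop("session trials need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(trials) != n_targets * n_blocks)
    stop(sprintf("incomplete session: expected %d trials (%d targets x %d blocks), got %d",
                 n_targets * n_blocks, n_targets, n_blocks, nrow(trials)), call. = FALSE)
  tab <- table(factor(trials$target, levels = seq_len(n_targets)),
               factor(trials$block, levels = seq_len(n_blocks)))
  if (!all(tab == 1L))
    stop("incomplete session: each target must appear exactly once per block", call. = FALSE)
  num <- as.matrix(trials[, c("robot_x", "robot_y", "match_x", "match_y")])
  if (any(!is.finite(num)))
    stop("trial coordinates must be finite", call. = FALSE)
  invisible(trials)
}

#' Compute the matching parameters of one session
#'
#' Six parameters summarise a 54-trial session, computed on matched positions
#' mirrored across the midline:
#' * `abs_error_xy` (mm): mean absolute mirrored-position error, x and y
#'   errors pooled over trials.
#' * `variability_xy` (mm): mean over the nine targets of the per-target
#'   standard deviations of matched positions, x and y pooled.
#' * `ratio_x`: span of per-target participant means between the three
#'   right-most and three left-most targets, divided by the robot span
#'   (contraction < 1, expansion > 1); `ratio_y` analogously with the
#'   proximal and distal target triples.
#' * `shift_x`, `shift_y` (mm): mean signed mirrored-position error.
#'
#' @param trials data frame with columns `target` (1-9), `block` (1-6),
#'   `robot_x`, `robot_y`, `match_x`, `match_y` (mm).
#' @param midline_x body midline (mm) used for mirroring.
#' @return named list of class `matching_parameters`.
#' @export
compute_matching_parameters <- function(trials, midline_x = 0) {
  validate_session(trials)
  mx <- 2 * midline_x - trials$match_x
  my <- trials$match_y
  dx <- mx - trials$robot_x
  dy <- my - trials$robot_y

  tgt <- factor(trials$target, levels = sort(unique(trials$target)))
  sd_x <- tapply(mx, tgt, sd)
  sd_y <- tapply(my, tgt, sd)

  mean_mx <- tapply(mx, tgt, mean)
  mean_my <- tapply(my, tgt, mean)
  rob_x <- tapply(trials$robot_x, tgt, mean)
  rob_y <- tapply(trials$robot_y, tgt, mean)

  ord_x <- order(rob_x)
  lft <- ord_x[1:3]; rgt <- ord_x[(length(ord_x) - 2):length(ord_x)]
  ord_y <- order(rob_y)
  prx <- ord_y[1:3]; dst <- ord_y[(length(ord_y) - 2):length(ord_y)]

  span <- function(v, hi, lo) mean(v[hi]) - mean(v[lo])
  ratio_x <- abs(span(mean_mx, rgt, lft)) / abs(span(rob_x, rgt, lft))
  ratio_y <- abs(span(mean_my, dst, prx)) / abs(span(rob_y, dst, prx))

  structure(list(
    abs_error_xy = mean(c(abs(dx), abs(dy))),
    variability_xy = mean(c(sd_x, sd_y)),
    shift_x = mean(dx),
    shift_y = mean(dy),
    ratio_x = ratio_x,
    ratio_y = ratio_y
  ), class = "matching_parameters")
}

apm_parameter_names <- function() {
  c("abs_error_xy", "variability_xy", "shift_x", "shift_y", "ratio_x", "ratio_y")
}

# Parameters that are strictly positive and modelled on the log scale.
apm_log_parameters <- function() {
  c("abs_error_xy", "variability_xy", "ratio_x", "ratio_y")
}

#' Fit the normative model on a control cohort
#'
#' Each matching parameter is regressed on age, sex and handedness in the
#' control cohort (log scale for the strictly positive parameters), yielding
#' per-parameter predictions and residual SDs that turn a new assessment into
#' covariate-adjusted Z-scores. Every control assessment is then pushed
#' through the full scoring chain to build the empirical normative
#' root-sum-square (RSS) sample against which Task Scores are standardised.
#'
#' @param cohort data frame with columns `age` (years), `sex` (0/1),
#'   `handedness` (-1/+1) and a list-column `session` of trial data frames
#'   (see [compute_matching_parameters()]). At least 30 assessments and both
#'   sexes are required.
#' @param midline_x body midline (mm).
#' @return an object of class `apm_normative_model`.
#' @export
normative_fit <- function(cohort, midline_x = 0) {
  stopifnot(is.data.frame(cohort), "session" %in% names(cohort))
  if (nrow(cohort) < 30)
    stop("normative fit needs >= 30 assessments", call. = FALSE)
  if (length(unique(cohort$sex)) < 2)
    stop("normative cohort must contain both sexes", call. = FALSE)
  for (v in c("age", "sex", "handedness"))
    if (length(unique(cohort[[v]])) < 2)
      stop(sprintf("degenerate design: covariate '%s' is constant", v), call. = FALSE)

  pn <- apm_parameter_names()
  P <- t(vapply(cohort$session,
                function(s) unlist(compute_matching_parameters(s, midline_x))[pn],
                numeric(length(pn))))
  colnames(P) <- pn

  X <- cbind(1, age = cohort$age, sex = cohort$sex, handedness = cohort$handedness)
  coefs <- matrix(NA_real_, 4, length(pn), dimnames = list(
    c("(Intercept)", "age", "sex", "handedness"), pn))
  sig <- setNames(numeric(length(pn)), pn)
  logp <- apm_log_parameters()
  for (p in pn) {
    v <- P[, p]
    if (p %in% logp) {
      if (any(v <= 0))
        stop(sprintf("parameter '%s' must be positive for its log pre-transform", p),
             call. = FALSE)
      v <- log(v)
    }
    fit <- lm.fit(X, v)
    coefs[, p] <- fit$coefficients
    dfres <- length(v) - fit$rank
    s <- sqrt(sum(fit$residuals^2) / dfres)
    sig[p] <- max(s, 1e-12)   # guards the zero-noise degenerate cohort
  }

  model <- structure(list(coefs = coefs, sigma = sig, log_params = logp,
                          param_names = pn, midline_x = midline_x,
                          n = nrow(cohort), rss_sample = NULL),
                     class = "apm_normative_model")
  rss <- vapply(seq_len(nrow(cohort)), function(i) {
    comp <- score_components(model, P[i, ], cohort[i, c("age", "sex", "handedness")])
    sqrt(sum(comp^2))
  }, numeric(1))
  model$rss_sample <- sort(rss)
  model
}

#' @export
print.apm_normative_model <- function(x, ...) {
  cat(sprintf("<apm_normative_model> fitted on %d assessments; normative RSS median %.3f\n",
              x$n, stats::median(x$rss_sample)))
  invisible(x)
}

#' Covariate-adjusted Z-score of one matching parameter
#'
#' @param model an [normative_fit()] result.
#' @param parameter parameter name (see `apm_parameter_names()`).
#' @param value observed parameter value.
#' @param covariates list or one-row data frame with `age`, `sex`,
#'   `handedness`.
#' @return numeric Z-score.
#' @export
zscore_parameter <- function(model, parameter, value, covariates) {
  stopifnot(inherits(model, "apm_normative_model"),
            parameter %in% model$param_names)
  tv <- value
  if (parameter %in% model$log_params) {
    if (any(value <= 0))
      stop(sprintf("parameter '%s' must be positive for its log pre-transform", parameter),
           call. = FALSE)
    tv <- log(value)
  }
  x <- c(1, covariates$age, covariates$sex, covariates$handedness)
  pred <- as.numeric(x %*% model$coefs[, parameter])
  (tv - pred) / model$sigma[[parameter]]
}

#' Zeta transform of a Z-score
#'
#' Folds a Z-score into a one-sided statistic with zero marking the best
#' possible performance: `zeta(z) = qnorm((pnorm(z) + 1) / 2)`. Strictly
#' increasing, non-negative, and for z ~ N(0,1) distributed as |N(0,1)|.
#'
#' @param z numeric Z-score(s).
#' @return numeric zeta score(s), >= 0.
#' @examples
#' zeta_transform(0)      # 0.6745
#' zeta_transform(1.96)   # 2.2414
#' @export
zeta_transform <- function(z) {
  # log-scale upper tail keeps the map finite for arbitrarily large |z|:
  # (pnorm(z)+1)/2 = 1 - pnorm(z, upper)/2
  qnorm(log(0.5) + pnorm(z, lower.tail = FALSE, log.p = TRUE),
        lower.tail = FALSE, log.p = TRUE)
}

#' Inverse of the zeta transform
#' @param zeta numeric zeta score(s), >= 0.
#' @return the Z-score(s) mapping to `zeta` under [zeta_transform()].
#' @export
zeta_inverse <- function(zeta) {
  # 2*pnorm(zeta) - 1 = 1 - 2*pnorm(zeta, upper)
  qnorm(log(2) + pnorm(zeta, lower.tail = FALSE, log.p = TRUE),
        lower.tail = FALSE, log.p = TRUE)
}

# Six one-sided/two-sided component scores from raw parameters + covariates:
# abs error and variability as zeta(z); systematic shift folded to |z|
# (direction-agnostic one-sided score, same null distribution as zeta(z));
# contraction/expansion ratios left as two-sided z.
score_components <- function(model, params, covariates) {
  z <- vapply(model$param_names,
              function(p) zscore_parameter(model, p, params[[p]], covariates),
              numeric(1))
  c(abs_error_xy = zeta_transform(z[["abs_error_xy"]]),
    variability_xy = zeta_transform(z[["variability_xy"]]),
    shift_x = abs(z[["shift_x"]]),
    shift_y = abs(z[["shift_y"]]),
    ratio_x = z[["ratio_x"]],
    ratio_y = z[["ratio_y"]])
}

# Rank-based inverse normal position of `v` in the sorted normative sample,
# ties broken by average rank; add-one denominator keeps p in (0, 1).
# Values beyond the sample range are mapped by linear extrapolation of the
# empirical quantile-quantile relationship (slope from the outer decile), so
# extreme performances stay ordered on an unbounded z scale instead of
# piling up at the ceiling rank.
rank_inverse_normal <- function(v, sample_sorted) {
  n <- length(sample_sorted)
  below <- findInterval(v, sample_sorted, left.open = TRUE)    # strictly less
  upto <- findInterval(v, sample_sorted)                       # less or equal
  p <- (below + (upto - below + 1) / 2) / (n + 1)
  z <- qnorm(p)
  hi <- sample_sorted[n]; lo <- sample_sorted[1]
  z_hi <- qnorm((n - 0.5) / (n + 1)); z_lo <- qnorm(1.5 / (n + 1))
  q90 <- quantile(sample_sorted, 0.9, names = FALSE, type = 1)
  q10 <- quantile(sample_sorted, 0.1, names = FALSE, type = 1)
  slope_hi <- (z_hi - qnorm(0.9)) / max(hi - q90, .Machine$double.eps)
  slope_lo <- (qnorm(0.1) - z_lo) / max(q10 - lo, .Machine$double.eps)
  up <- v > hi; dn <- v < lo
  z[up] <- z_hi + slope_hi * (v[up] - hi)
  z[dn] <- z_lo - slope_lo * (lo - v[dn])
  z
}

#' APM Task Score of one session
#'
#' The full scoring chain: matching parameters -> covariate-adjusted Z-scores
#' -> one-sided (zeta / folded) or two-sided components -> root-sum-square
#' (RSS) -> standardisation of the RSS against the normative RSS sample by a
#' rank-based inverse-normal map -> final zeta transform. The Task Score is
#' one-sided with 0 the best possible performance and shares its percentiles
#' with a standard normal; scores above `threshold` (default 1.96, the 95th
#' percentile of the one-sided score) classify the assessment as impaired.
#'
#' @param session trial data frame (see [compute_matching_parameters()]).
#' @param covariates list/row with `age`, `sex`, `handedness`.
#' @param model an [normative_fit()] result.
#' @param threshold impairment cut on the Task Score.
#' @return list of class `task_score_result`: `parameters`, `z`,
#'   `components`, `rss`, `task_score`, `impaired`.
#' @export
task_score <- function(session, covariates, model, threshold = 1.96) {
  stopifnot(inherits(model, "apm_normative_model"))
  params <- compute_matching_parameters(session, model$midline_x)
  z <- vapply(model$param_names,
              function(p) zscore_parameter(model, p, params[[p]], covariates),
              numeric(1))
  comp <- score_components(model, params, covariates)
  rss <- sqrt(sum(comp^2))
  z_rss <- rank_inverse_normal(rss, model$rss_sample)
  score <- zeta_transform(z_rss)
  structure(list(parameters = params, z = z, components = comp, rss = rss,
                 task_score = score, impaired = score > threshold),
            class = "task_score_result")
}

#' Score every session of a cohort
#'
#' @param cohort data frame with covariate columns (`age`, `sex`,
#'   `handedness`) and a `session` list-column; any other columns are
#'   carried through.
#' @param model an [normative_fit()] result.
#' @param threshold impairment cut.
#' @return the cohort data frame (without the `session` column) with the six
#'   parameters, `rss`, `task_score` and `impaired` appended.
#' @export
score_cohort <- function(cohort, model, threshold = 1.96) {
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    ts <- task_score(cohort$session[[i]],
                     cohort[i, c("age", "sex", "handedness")],
                     model, threshold)
    c(unlist(ts$parameters), rss = ts$rss,
      task_score = ts$task_score, impaired = as.numeric(ts$impaired))
  })
  out <- cbind(cohort[, setdiff(names(cohort), "session"), drop = FALSE],
               do.call(rbind, res))
  out$impaired <- out$impaired > 0
  out
}
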