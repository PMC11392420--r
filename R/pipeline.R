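#' Configuration for a full synthetic study run
#'
#' Collects every printed constant of the emulated study design with its
#' default: 203 participants (118:85 right:left), 2227 normative assessments
#' from 799 controls, impairment cut 1.96, FDR level 0.05, inclusion bound
#' 25, 4000 permutations, TFCE E = 0.5 / H = 2.
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param shape,voxel_size,n_tracts,n_controls toy-brain geometry, see
#'   [make_brain()].
#' @param n_stroke,p_right stroke cohort size and right-lesion probability.
#' @param n_norm_controls,n_norm_assessments normative cohort sizes.
#' @param truth a [ground_truth()].
#' @param impairment_threshold Task Score impairment cut.
#' @param fdr_q FDR level.
#' @param inclusion_min_n tract inclusion bound (strict).
#' @param n_perm TFCE permutations (>= 1).
#' @param tfce_e,tfce_h TFCE exponents.
#' @param write_maps write per-participant disconnectome NIfTIs.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       shape = c(32L, 38L, 32L), voxel_size = 3,
                       n_tracts = 6L, n_controls = 10L,
                       n_stroke = 203L, p_right = 118 / 203,
                       n_norm_controls = 799L, n_norm_assessments = 2227L,
                       truth = ground_truth(),
                       impairment_threshold = 1.96,
                       fdr_q = 0.05, inclusion_min_n = 25,
                       n_perm = 4000L, tfce_e = 0.5, tfce_h = 2,
                       write_maps = TRUE) {
  stopifnot(impairment_threshold > 0, fdr_q > 0, inclusion_min_n > 0,
            n_perm >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields override [run_config()] defaults; `truth` may be given as a
#' nested list with the [ground_truth()] fields.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$truth)) {
    tr <- raw$truth
    ct <- unlist(tr$causal_tracts %||% numeric(0))
    args <- tr[setdiff(names(tr), "causal_tracts")]
    raw$truth <- do.call(ground_truth, c(list(causal_tracts = ct), args))
  }
  do.call(run_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the whole pipeline on one synthetic study
#'
#' simulate -> score -> lesion load -> disconnectome -> voxelwise stats ->
#' cohort stats, writing every artefact plus a manifest (with content
#' hashes, stage seeds and wall-clock times) into `outdir`. Deterministic
#' given the config seed.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing).
#' @param verbose log stage progress.
#' @return invisibly, a list with the in-memory results (`brain`, `model`,
#'   `cohort`, `scores`, `stats`, `tfce`, `manifest`).
#' @export
run_all <- function(config = run_config(), outdir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  seeds <- list(brain = config$seed, normative = config$seed + 1L,
                cohort = config$seed + 2L, perm = config$seed + 3L)
  written <- character(0)
  keep <- function(path) { written <<- c(written, path); path }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  stage_log(verbose, "simulate: brain (seed %d)", seeds$brain)
  brain <- run_stage("simulate", make_brain(
    seeds$brain, config$shape, config$voxel_size,
    config$n_tracts, config$n_controls))
  bd <- file.path(outdir, "brain"); dir.create(bd, showWarnings = FALSE)
  for (nm in names(brain$tract_maps))
    keep(write_volume(brain$tract_maps[[nm]], file.path(bd, paste0(nm, ".nii.gz"))))
  keep(write_volume(brain$gm_mask, file.path(bd, "gm_mask.nii.gz")))
  keep(write_volume(brain$brain_mask, file.path(bd, "brain_mask.nii.gz")))
  cd <- file.path(outdir, "controls"); dir.create(cd, showWarnings = FALSE)
  for (ctrl in brain$controls)
    keep(write_streamlines(ctrl, file.path(cd, paste0(ctrl$control_id, ".txt"))))

  stage_log(verbose, "simulate: normative cohort (%d assessments, seed %d)",
            config$n_norm_assessments, seeds$normative)
  normative <- run_stage("simulate", make_normative_cohort(
    seeds$normative, config$n_norm_controls, config$n_norm_assessments,
    trial_model = config$truth$trial_model))

  stage_log(verbose, "simulate: stroke cohort (n = %d, seed %d)",
            config$n_stroke, seeds$cohort)
  cohort <- run_stage("simulate", make_stroke_cohort(
    seeds$cohort, brain, config$truth, config$n_stroke, config$p_right))
  ld <- file.path(outdir, "lesions"); dir.create(ld, showWarnings = FALSE)
  for (i in seq_along(cohort$lesions))
    keep(write_volume(cohort$lesions[[i]],
                      file.path(ld, sprintf("lesion%03d.nii.gz", i))))
  trials <- do.call(rbind, lapply(seq_along(cohort$sessions), function(i)
    cbind(participant_id = i, cohort$sessions[[i]])))
  keep(file.path(outdir, "trials.csv"))
  write.csv(trials, file.path(outdir, "trials.csv"), row.names = FALSE)

  stage_log(verbose, "score: normative fit + cohort scoring")
  model <- run_stage("score", normative_fit(normative))
  scores <- run_stage("score", score_cohort(cohort_sessions(cohort), model,
                                            config$impairment_threshold))
  scores$side <- cohort$table$side
  keep(file.path(outdir, "scores.csv"))
  write.csv(scores, file.path(outdir, "scores.csv"), row.names = FALSE)

  stage_log(verbose, "lesionload: %d tract maps x %d lesions",
            length(brain$tract_maps), length(cohort$lesions))
  loads <- run_stage("lesionload", tract_load_table(
    cohort$lesions, brain$tract_maps, brain$gm_mask))
  keep(file.path(outdir, "loads.csv"))
  write.csv(loads, file.path(outdir, "loads.csv"), row.names = FALSE)

  stage_log(verbose, "disconnectome: %d maps from %d controls",
            length(cohort$lesions), length(brain$controls))
  rasterized <- lapply(brain$controls, rasterize_streamline_set,
                       grid = brain$grid)
  maps <- run_stage("disconnectome", lapply(cohort$lesions, disconnectome_map,
                                            controls = brain$controls,
                                            grid = brain$grid,
                                            rasterized = rasterized))
  if (isTRUE(config$write_maps)) {
    dd <- file.path(outdir, "disconnectome"); dir.create(dd, showWarnings = FALSE)
    for (i in seq_along(maps))
      keep(write_volume(maps[[i]], file.path(dd, sprintf("map%03d.nii.gz", i))))
  }

  stage_log(verbose, "stats: ANCOVA, chi-square, tract battery, PCA")
  stats_res <- run_stage("stats", {
    anc <- ancova_side(scores$task_score, cohort$table$side,
                       cohort$table$total_lesion_cc)
    tab <- table(factor(cohort$table$side, levels = c("left", "right")),
                 factor(cohort$table$ipsi_impaired, levels = c(TRUE, FALSE)))
    chi <- chi_square_2x2(tab)
    battery <- tract_regression_battery(scores$task_score, loads,
                                        cohort$table$side, loads$gm_lesion_cc,
                                        min_n = config$inclusion_min_n,
                                        q = config$fdr_q)
    fl <- family_loads(loads, battery$included)
    pca <- pca_predictors(cbind(fl, gm_lesion_cc = loads$gm_lesion_cc))
    pcr <- pc_regression(pca, scores$task_score, q = config$fdr_q)
    list(ancova = anc, chi_square = chi, battery = battery,
         pca = pca, pc_regression = pcr)
  })
  keep(file.path(outdir, "tract_regression.csv"))
  write.csv(stats_res$battery$tests, file.path(outdir, "tract_regression.csv"),
            row.names = FALSE)
  keep(file.path(outdir, "pca_loadings.csv"))
  write.csv(data.frame(predictor = rownames(stats_res$pca$loadings),
                       stats_res$pca$loadings, check.names = FALSE),
            file.path(outdir, "pca_loadings.csv"), row.names = FALSE)
  keep(file.path(outdir, "pc_regression.csv"))
  write.csv(stats_res$pc_regression$coef, file.path(outdir, "pc_regression.csv"),
            row.names = FALSE)

  stage_log(verbose, "voxelstats: TFCE with %d permutations (seed %d)",
            config$n_perm, seeds$perm)
  vres <- run_stage("voxelstats", group_difference_tfce(
    maps, scores$impaired, covariate = cohort$table$gm_lesion_cc,
    n_perm = config$n_perm, E = config$tfce_e, H = config$tfce_h,
    seed = seeds$perm))
  vd <- file.path(outdir, "voxelstats"); dir.create(vd, showWarnings = FALSE)
  keep(write_volume(vres$t_map, file.path(vd, "t_map.nii.gz")))
  keep(write_volume(vres$tfce_map, file.path(vd, "tfce_map.nii.gz")))
  keep(write_volume(vres$p_fwe, file.path(vd, "p_fwe.nii.gz")))
  keep(write_volume(vres$sig_mask, file.path(vd, "sig_p05.nii.gz")))
  keep(write_volume(vres$peak_mask, file.path(vd, "sig_p001.nii.gz")))

  summary_json <- list(
    seed = config$seed, stage_seeds = seeds,
    n_stroke = config$n_stroke,
    n_impaired = sum(scores$impaired),
    ancova = stats_res$ancova[c("F", "p")],
    chi_square = stats_res$chi_square[c("chi2", "p")],
    included_tracts = stats_res$battery$included,
    fdr_significant = subset(stats_res$battery$tests, significant,
                             select = c("tract", "term"))[],
    pca_selected = stats_res$pca$selected,
    n_sig_voxels = sum(vres$sig_mask$values),
    n_peak_voxels = sum(vres$peak_mask$values),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  keep(file.path(outdir, "summary.json"))
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- data.frame(
    file = sub(paste0("^", outdir, "/?"), "", written),
    md5 = unname(tools::md5sum(written))
  )
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  stage_log(verbose, "done in %.1f s; %d files in manifest",
            summary_json$elapsed_s, nrow(manifest))

  invisible(list(brain = brain, model = model, cohort = cohort,
                 scores = scores, loads = loads, maps = maps,
                 stats = stats_res, tfce = vres, manifest = manifest,
                 config = config))
}
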