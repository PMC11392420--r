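# propriomap

Lesion-symptom and disconnectome mapping for robotic proprioception
assessment after unilateral stroke.

About half of stroke survivors lose some sense of where their arm is —
proprioception — and the white-matter disconnections behind that loss are
poorly understood. `propriomap` implements, end to end, the analysis that
links the two: scoring of a robotic **arm position matching (APM)** task
against a normative cohort, **white-matter tract lesion load** from NIfTI
lesion masks and a probabilistic tract atlas, **disconnectome probability
maps** built from lesion-intersecting control streamlines, and the full
statistical battery — lesion-side ANCOVA, chi-square association,
standardized tract-wise regressions with Benjamini-Hochberg FDR control,
principal-component regression, and voxelwise group inference with
threshold-free cluster enhancement (TFCE) under Freedman-Lane permutation.
A synthetic study generator with known ground truth makes every stage
testable without any imaging download.

## The models in brief

A 54-trial APM session (9 targets x 6 blocks; the robot moves the affected
arm, the participant mirror-matches) is summarised by six parameters
(absolute error, variability, x/y contraction ratios, x/y systematic
shift). Each is turned into a covariate-adjusted Z-score against a
normative regression on age, sex and handedness, folded one-sided where
zero means best performance (zeta transform `ζ(z) = Φ⁻¹((Φ(z)+1)/2)`), and
combined as a root-sum-square that is rank-standardised against the
normative RSS sample and zeta-transformed into the **Task Score**; scores
above 1.96 (the 95th percentile of the one-sided scale) classify
impairment.

Tract lesion load is `100·|lesion ∩ tract| / |tract|`. A participant's
disconnectome map holds, at each voxel, the percentage of N control
subjects (N = 10 in the emulated design) with a streamline that crosses
both the lesion and that voxel. Group differences are tested with
`t`-statistics enhanced by TFCE (`E = 0.5`, `H = 2`, 6-connectivity) and
FWE-corrected by the permutation null of the image-wide maximum (4000
permutations by default; masks at corrected p < 0.05 and p < 0.001).

See `vignettes/methods.Rmd` for the full account.

## Worked example

```r
library(propriomap)

brain    <- make_brain(seed = 1, n_tracts = 4, n_controls = 10)
controls <- make_normative_cohort(seed = 2, n_controls = 120, n_assessments = 160)
model    <- normative_fit(controls)

truth  <- ground_truth(causal_tracts = c(tract1 = 0.5))   # tract1 is causal
cohort <- make_stroke_cohort(seed = 3, brain, truth, n = 150)
scores <- score_cohort(cohort_sessions(cohort), model)
sum(scores$impaired)
#> [1] 113

battery <- tract_regression_battery(scores$task_score, cohort$table,
                                    cohort$table$side, cohort$table$gm_lesion_cc,
                                    min_n = 10)
subset(battery$tests, term == "load")[, c("tract", "estimate", "p_adjusted", "significant")]
#>     tract estimate p_adjusted significant
#> 2  tract1   0.3742   0.000273        TRUE
#> 21 tract2  -0.0118   0.910364       FALSE
#> 22 tract3   0.3244   0.002398        TRUE
#> 23 tract4  -0.1531   0.110701       FALSE
```

113 of 150 synthetic participants cross the 1.96 impairment cut. The
causal tract (`tract1`) survives FDR correction with a positive
standardized coefficient — more damage, worse score — and so does its
spatial neighbour `tract3`, whose lesion load is collinear with `tract1`'s
(r ≈ 0.9): the same collinearity that motivates the principal-component
follow-up in real cohorts, where here only PC1 relates to the Task Score:

```r
pca <- pca_predictors(cbind(family_loads(cohort$table), gm = cohort$table$gm_lesion_cc))
pc_regression(pca, scores$task_score)$coef[2, c("term", "estimate", "p", "significant")]
#>   term estimate        p significant
#> 2  PC1   -0.305 5.93e-12        TRUE
```

Disconnectome maps and voxelwise TFCE inference run the same way:

```r
maps <- lapply(cohort$lesions, disconnectome_map,
               controls = brain$controls, grid = brain$grid)
vox <- group_difference_tfce(maps, scores$impaired, cohort$table$gm_lesion_cc,
                             n_perm = 500, seed = 4)
vox
#> <tfce_result> 500 permutations; 2078 voxels analysed; 0 significant (FWE p<0.05), 0 at peak p<0.001
```

A full simulate → score → lesionload → disconnectome → voxelstats → stats
run with a manifest is one call (`run_all(run_config(seed = 1), "outdir")`),
also exposed as the `inst/cli/proprio-disconnect` command-line wrapper with
`simulate | score | lesionload | disconnectome | voxelstats | stats |
run-all` subcommands and `--config`/`--seed`/`--outdir` flags (YAML/JSON
config, see `inst/extdata/example-config.yaml`).

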