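---
title: "Models and methods: from matching trials to disconnectome inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from matching trials to disconnectome inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propriomap)
```

`propriomap` implements a complete lesion-behaviour analysis linking
white-matter disconnection after unilateral stroke to proprioceptive
impairment measured with a robotic arm position matching (APM) task. This
vignette is the package's account of the underlying models: what each stage
computes, which knobs matter, and what the synthetic validation does and does
not establish.

## The APM task and its composite score

In the APM task a robot passively moves the stroke-affected arm to one of
nine targets (a 3 x 3 square) and the participant mirror-matches with the
opposite arm, without vision; each target is tested once in each of six
blocks, giving 54 trials. Six parameters summarise a session after the
matched positions are reflected across the body midline (`mirror_match()`):

* **absolute error** (mm) — mean |error|, x and y pooled over trials;
* **variability** (mm) — mean over targets of the per-target SDs of matched
  positions, x and y pooled;
* **contraction/expansion ratios** (x and y) — the participant's span
  between the three left-/right-most (or proximal/distal) target triples
  over the robot's span;
* **systematic shift** (mm, x and y) — mean signed error.

Each parameter is compared against a normative model fitted on a control
cohort (the emulated design: 2227 assessments from 799 controls): a linear
regression on age, sex and handedness, on the log scale for the strictly
positive parameters (absolute error, variability, both ratios), with the
residual SD turning a new observation into a covariate-adjusted Z-score.
One-sided parameters are folded so that zero marks the best possible
performance: absolute error and variability through the zeta transform
`zeta(z) = qnorm((pnorm(z) + 1)/2)`, and the signed shifts through `|z|`,
which for a standard-normal null has exactly the same half-normal
distribution as `zeta(z)`; the two-sided ratios stay as Z-scores. The
root-sum-square (RSS) of the six components is then standardised against
the empirical normative RSS sample by a rank-based inverse-normal map
(ties by average rank) and zeta-transformed into the final one-sided **Task
Score**. By construction the score shares its percentiles with a standard
normal, so scores above 1.96 — the 95th percentile of the one-sided scale —
classify the assessment as impaired, and about 5% of held-out controls
cross that cut.

Two numerical choices matter here. First, the zeta transform is evaluated
through log-scale normal tails so it stays finite for arbitrarily extreme
Z-scores. Second, the rank-based map is linearly extrapolated beyond the
normative sample range (slope taken from the outer decile of the
quantile-quantile relationship): severely impaired performances would
otherwise all collapse onto the ceiling rank of the finite normative
sample, destroying the severity ordering that the cohort regressions rely
on. Within the normative range the map is purely empirical, so the
impairment calibration is untouched.

The proprietary analysis suite behind the original task does not disclose
its pre-transforms; the log-linear normative surrogate used here is
deliberately transparent and is exposed through the model object. A related
open question is whether x and y are pooled into single error/variability
parameters; this implementation pools them (six components in total), which
keeps the x/y shifts separable while matching the published parameter list.

## Lesion load, grey-matter volume, and the inclusion filter

Tract lesion load is the percentage of a tract's voxels overlapped by the
lesion, with the probabilistic atlas binarised at a configurable threshold
(default: any support, > 0 — the simplest reading of voxel-count loads; a
probability-weighted variant is deliberately out of scope). Grey-matter
lesion volume is the lesion / grey-matter-mask overlap in cc. For the
cohort regressions a tract *family* enters only when strictly more than 25
participants show damage (load > 0) to the left homologue and more than 25
to the right one; on the emulated full design this rule yields the 23
analysed families. Families are paired by a `_left`/`_right` naming
convention, and the single per-family predictor is the damaged-side
(maximum) homologue load, since lesions are unilateral.

## Disconnectome maps

Per-control tractography is emulated by intersection against precomputed
streamline sets: a control's visitation map marks every voxel traversed by
a streamline of that control that also crosses a lesion voxel. Streamlines
are rasterised by exact 3D voxel traversal (each segment cut at every
half-integer boundary plane in continuous voxel coordinates), so the voxel
set is deterministic and contains every voxel a dense sampling of the line
would visit. Binarising and averaging the visitation maps of all `N`
controls (any visitation counts, i.e. a >= 1-streamline threshold) gives
the disconnectome map in percent: each voxel holds a multiple of `100/N`
between 0 and 100. Per-control native-space normalisation and actual
diffusion tracking are out of scope; the streamline sets stand in for them.

## Voxelwise inference: TFCE and Freedman-Lane permutation

Group differences in disconnection (impaired > unimpaired, a one-sided
contrast) are tested voxelwise with a linear model including a grey-matter
lesion-volume covariate, enhanced by threshold-free cluster enhancement
(TFCE) with the published defaults E = 0.5, H = 2, 6-connectivity, and 100
integration steps; the step height is `max(t)/100` per map, with midpoint
thresholds `h_k = (k - 1/2) dh`, which reproduces the analytic single-peak
integral `h^3/3` to well under 1%. Family-wise error is controlled through
the permutation distribution of the image-wide maximum TFCE score under
Freedman-Lane residual permutation (the nuisance-only model's residuals are
permuted and re-added to its fitted values), which reduces to simple label
permutation when no covariate is present. The observed statistic is
included in its own null (add-one rule), so corrected p-values live in
`{1/(n_perm+1), ..., 1}`; the emulated design uses 4000 permutations with
significance masks at corrected p < 0.05 and a stricter post-hoc peak mask
at p < 0.001. Only voxels whose values vary across participants are tested.
The TFCE core is compiled (incremental union-find over voxels sorted by
value), keeping thousands of permutations at seconds scale.

## Cohort statistics

* **Side ANCOVA** — Task Score ~ lesion side + total lesion volume; the
  partial (type-III) F for side. Total (rather than grey-matter) lesion
  volume is used here because this comparison exists to absorb
  lesion-*size* differences between hemisphere groups.
* **Hemisphere association** — Pearson chi-square without continuity
  correction on the 2 x 2 ipsilesional-impairment x hemisphere table.
* **Tract-wise regressions** — per included family, OLS of the
  (standardized) Task Score on standardized lesion load, lesion side
  (left = 0, right = 1, so positive coefficients mean worse scores with
  right lesions) and standardized grey-matter lesion volume; R-squared and
  Cohen's f2 = R2/(1 - R2) are reported, and all non-intercept coefficient
  tests pool into one Benjamini-Hochberg family (3 x 23 = 69 tests on the
  full design) at q = 0.05. A variant without the grey-matter covariate is
  available by passing `gm_volume = NULL`.
* **Principal component regression** — eigendecomposition of the
  correlation matrix of the 24 standardized predictors (23 family loads +
  grey-matter volume); the smallest component count reaching 95% cumulative
  variance enters an OLS on the Task Score with BH correction over those
  component tests. Sample (n-1) SDs are used everywhere so standardization
  is bit-reproducible.

## The synthetic study and its ground truth

The generator builds a miniature but complete study on a 32 x 38 x 32 grid
of 3 mm voxels (seconds-scale end-to-end, yet large enough for eight or
more tube tracts): an ellipsoidal brain with a grey-matter shell,
left/right homologous pairs of curved tubular tract probability maps, ten
control streamline sets jittered around the tract centrelines, and
ellipsoidal lesions confined to one hemisphere, sized to a target volume
drawn from a log-normal matched to the emulated cohort's 30.5 +- 39.3 cc.
Cohort composition follows the emulated study: 203 participants at a
118:85 right:left split, ages ~ N(62, 14).

Ground truth is an additive latent severity,
`intercept + side_effect * right + sum(beta_t * std(load_t)) + gm_effect * std(gm) + noise`,
expressed in normative-SD units. The trial model maps severity `s` to the
three canonical phenotypes with one knob each: a `10 s` mm systematic
shift, a workspace contraction of `max(0.2, 1 - 0.1 s)`, and per-coordinate
trial noise of `5 + 3 s` mm. The latent score enters the trial model
directly rather than after per-cohort re-standardisation: re-scaling
within each cohort would erase the baseline offset and make the meaning of
`beta` depend on cohort composition, and would give "null" cohorts a
severity spread by construction. On top of severity, the generator draws
the between-subject baseline variation real cohorts show even in controls —
an idiosyncratic shift (SD 3 mm), workspace scaling (SD 0.05) and a
log-normal trial-noise multiplier (SD 0.15) — plus mild covariate effects
(trial noise increasing by 0.02 mm/year of age and 0.3 mm with sex;
handedness nudging shift by 0.5 mm), all well under 0.3 SD across the
covariate range so that covariate adjustment is exercised without
dominating. Without the between-subject terms the normative residual SDs
would be set by trial noise alone (a fraction of a millimetre after
averaging 54 trials), making any severity implausibly detectable. The
default intercept of 0.8 places roughly three of five participants above
the impairment cut, the neighbourhood of the emulated cohort's 127 of 203.

What the synthetic cohorts do *not* emulate: vascular-territory lesion
shapes, spatial normalisation error, realistic diffusion geometry, and the
deep anatomical collinearity structure of a real atlas. Passing tests
therefore establish the *estimators'* calibration and recovery behaviour,
not anatomical claims about real cohorts.

One structural property deserves emphasis: nearby tracts share lesions, so
family loads are strongly collinear (the central motivation for the
principal-component analysis). When several tracts are causal at once, the
one-tract-at-a-time regression is a misspecified model of the latent
process, and conditioning on grey-matter volume makes the omitted causal
load *negatively* partial-correlated with the included one — its
coefficient is then biased regardless of sample size. The coefficient
recovery suite therefore runs under a single causal tract, where the
per-tract regression is correctly specified and coverage is exact; with
the causal coefficient defined on the latent scale, recovery is assessed
on the stored latent severity, while the FDR-detection half of the same
suite runs on the fully measured Task Scores.

## Problem sizes and seeds

All stochastic stages take explicit integer seeds and are bit-reproducible.
The validation suites run at deliberately chosen desk scales: normative
calibration at the full 799-control / 2227-assessment design with 600
held-out controls; voxelwise type-I error across 20 seeded null cohorts of
30 participants at 500 permutations; regression-null uniformity over 1000
replicates; and recovery over 50 replicate 400-participant cohorts. The
default pipeline configuration (`run_config()`) carries every emulated
study constant — 203 participants, impairment cut 1.96, FDR 5%, inclusion
bound 25, 4000 permutations, TFCE E = 0.5 / H = 2.

## Known limitations

* The normative surrogate is log-linear; the original proprietary
  transforms are undocumented and may differ in tail behaviour.
* Tail extrapolation of the rank map is linear; severe scores far beyond
  the normative range are ordered correctly but their absolute values are a
  modelling choice.
* Lesion blobs are convex; loads are computed on binarised atlas support.
* With fewer controls the disconnectome percentage scale is coarse
  (multiples of 100/N), which the voxelwise linear model treats as
  continuous.
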