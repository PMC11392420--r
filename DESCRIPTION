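Package: propriomap
Title: Lesion Load, Disconnectome Mapping and Robotic Proprioception Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Links white-matter disconnection after unilateral stroke to
    proprioceptive impairment measured with a robotic arm position matching
    (APM) task. Provides APM task scoring against a normative cohort (parameter
    Z-scores, zeta transforms, root-sum-square Task Score, impairment
    classification), white-matter tract lesion load and grey-matter lesion
    volume from NIfTI masks, lesion-seeded disconnectome probability maps from
    control streamline sets, voxelwise group inference with threshold-free
    cluster enhancement and Freedman-Lane permutation, cohort statistics
    (ANCOVA, chi-square, standardized tract-wise regressions with BH-FDR,
    principal component regression), and a synthetic study generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
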