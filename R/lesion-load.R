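#' White-matter tract lesion load
#'
#' Percentage of a tract's voxels overlapped by the lesion: the probabilistic
#' atlas map is binarised at `threshold` (default: any atlas support counts)
#' and the load is `100 * |lesion AND tract| / |tract|`. Monotone under lesion
#' growth and invariant to lesion voxels outside the tract.
#'
#' @param lesion binary lesion [volume_grid].
#' @param tract tract probability [volume_grid] (values 0-1), on the same
#'   grid as `lesion`.
#' @param threshold binarisation threshold on the tract probability; voxels
#'   with probability strictly greater are counted.
#' @return numeric lesion load in percent (0-100).
#' @export
tract_lesion_load <- function(lesion, tract, threshold = 0) {
  assert_mask(lesion)
  stop_if_incompatible(lesion, tract, "lesion and tract")
  tmask <- tract$values > threshold
  ntract <- sum(tmask)
  if (ntract == 0)
    stop("empty tract mask: lesion load undefined", call. = FALSE)
  100 * sum(lesion$values == 1 & tmask) / ntract
}

#' Grey-matter lesion volume
#'
#' Overlap of the lesion with the grey-matter segmentation, in cc.
#'
#' @param lesion binary lesion [volume_grid].
#' @param gm_mask binary grey-matter [volume_grid] on the same grid.
#' @return numeric volume in cc.
#' @export
grey_matter_lesion_volume <- function(lesion, gm_mask) {
  assert_mask(lesion); assert_mask(gm_mask)
  stop_if_incompatible(lesion, gm_mask, "lesion and grey-matter mask")
  sum(lesion$values == 1 & gm_mask$values == 1) * voxel_volume_mm3(lesion) / 1000
}

#' Per-participant table of tract loads and lesion volumes
#'
#' @param lesions list of binary lesion [volume_grid]s.
#' @param tract_maps named list of tract probability volumes (names carry the
#'   `_left` / `_right` homologue suffix).
#' @param gm_mask binary grey-matter volume.
#' @param threshold tract binarisation threshold.
#' @return data frame: `participant_id`, one load column per tract map,
#'   `gm_lesion_cc`, `total_lesion_cc`.
#' @export
tract_load_table <- function(lesions, tract_maps, gm_mask, threshold = 0) {
  stopifnot(is.list(lesions), length(lesions) >= 1, length(tract_maps) >= 1)
  for (l in lesions) {
    assert_mask(l)
    stop_if_incompatible(l, tract_maps[[1]], "lesion and tract maps")
  }
  # binarise each tract once; loads are then plain index sums
  tidx <- lapply(tract_maps, function(tm) which(tm$values > threshold))
  if (any(lengths(tidx) == 0))
    stop("empty tract mask: lesion load undefined", call. = FALSE)
  loads <- vapply(tidx, function(ix)
    vapply(lesions, function(l) 100 * sum(l$values[ix]) / length(ix), numeric(1)),
    numeric(length(lesions)))
  if (is.null(dim(loads))) loads <- matrix(loads, nrow = 1,
                                           dimnames = list(NULL, names(tract_maps)))
  out <- data.frame(participant_id = seq_along(lesions))
  out <- cbind(out, as.data.frame(loads))
  out$gm_lesion_cc <- vapply(lesions, grey_matter_lesion_volume, numeric(1),
                             gm_mask = gm_mask)
  out$total_lesion_cc <- vapply(lesions, mask_volume_cc, numeric(1))
  out
}

# Split "<family>_<side>" map names into a family/side table, erroring on
# unpaired labels.
homologue_pairs <- function(map_names) {
  side <- ifelse(grepl("_left$", map_names), "left",
                 ifelse(grepl("_right$", map_names), "right", NA))
  if (any(is.na(side)))
    stop("tract labels must end in '_left' or '_right': ",
         paste(map_names[is.na(side)], collapse = ", "), call. = FALSE)
  fam <- sub("_(left|right)$", "", map_names)
  for (f in unique(fam)) {
    s <- side[fam == f]
    if (!all(c("left", "right") %in% s))
      stop(sprintf("unpaired tract label: family '%s' lacks a %s homologue",
                   f, setdiff(c("left", "right"), s)), call. = FALSE)
  }
  data.frame(map = map_names, family = fam, side = side)
}

#' Tract inclusion filter for the regression battery
#'
#' To keep per-tract regressions from running on sparse data, a tract family
#' enters the analysis only when *more than* `min_n` participants have damage
#' (load > 0) to the left homologue AND more than `min_n` to the right
#' homologue. On the emulated study design this rule yields 23 analysed
#' tract families.
#'
#' @param loads data frame of per-participant loads with columns named
#'   `<family>_left` / `<family>_right` (e.g. from [tract_load_table()]).
#' @param min_n strict lower bound on damaged-participant counts per side.
#' @return character vector of included family names.
#' @export
tract_inclusion_filter <- function(loads, min_n = 25) {
  stopifnot(is.data.frame(loads), nrow(loads) >= 1)
  cols <- grep("_(left|right)$", names(loads), value = TRUE)
  if (!length(cols)) stop("no '<family>_left/_right' load columns found", call. = FALSE)
  pairs <- homologue_pairs(cols)
  fams <- unique(pairs$family)
  keep <- vapply(fams, function(f) {
    nl <- sum(loads[[paste0(f, "_left")]] > 0)
    nr <- sum(loads[[paste0(f, "_right")]] > 0)
    nl > min_n && nr > min_n
  }, logical(1))
  fams[keep]
}

#' Combine homologue loads into one predictor per tract family
#'
#' The cohort regressions and the PCA use a single lesion-load predictor per
#' tract family; with unilateral lesions this is the load of the damaged
#' (larger-load) homologue.
#'
#' @param loads data frame with `<family>_left` / `<family>_right` columns.
#' @param families families to combine; default all present.
#' @return data frame of per-family loads.
#' @export
family_loads <- function(loads, families = NULL) {
  cols <- grep("_(left|right)$", names(loads), value = TRUE)
  pairs <- homologue_pairs(cols)
  if (is.null(families)) families <- unique(pairs$family)
  out <- lapply(families, function(f)
    pmax(loads[[paste0(f, "_left")]], loads[[paste0(f, "_right")]]))
  names(out) <- families
  as.data.frame(out)
}
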