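#' Visitation map of one control for one lesion
#'
#' Emulates lesion-seeded tractography against a precomputed control
#' streamline set: a voxel is visited when some streamline of this control
#' both intersects a lesion voxel and passes through that voxel. Streamlines
#' are rasterised with [rasterize_streamline()]; an empty lesion yields an
#' all-zero map.
#'
#' @param lesion binary lesion [volume_grid].
#' @param control a [streamline_set].
#' @param grid the common [volume_grid] space.
#' @param rasterized optional precomputed [rasterize_streamline_set()] result
#'   for `control` on `grid` (reused across lesions for speed).
#' @return binary [volume_grid] visitation map.
#' @export
visitation_map <- function(lesion, control, grid, rasterized = NULL) {
  assert_mask(lesion)
  stop_if_incompatible(lesion, grid, "lesion and reference grid")
  if (is.null(rasterized)) rasterized <- rasterize_streamline_set(control, grid)
  inside <- lesion$values == 1
  vals <- logical(length(grid$values))
  for (vox in rasterized) {
    if (any(inside[vox])) vals[vox] <- TRUE
  }
  with_values(grid, as.numeric(vals))
}

#' Disconnectome probability map of one participant
#'
#' Binarised visitation maps of all `N` controls are averaged and scaled to
#' percent: each voxel holds `100 * (number of controls whose
#' lesion-intersecting streamlines pass through it) / N`, a multiple of
#' `100/N` between 0 and 100.
#'
#' @param lesion binary lesion [volume_grid].
#' @param controls list of at least two [streamline_set]s.
#' @param grid the common [volume_grid] space.
#' @param rasterized optional list of precomputed
#'   [rasterize_streamline_set()] results, one per control.
#' @return [volume_grid] with values in 0-100 (% of controls).
#' @export
disconnectome_map <- function(lesion, controls, grid, rasterized = NULL) {
  stopifnot(is.list(controls), length(controls) >= 2)
  if (is.null(rasterized))
    rasterized <- lapply(controls, rasterize_streamline_set, grid = grid)
  acc <- numeric(length(grid$values))
  for (i in seq_along(controls)) {
    vm <- visitation_map(lesion, controls[[i]], grid, rasterized[[i]])
    acc <- acc + vm$values
  }
  with_values(grid, 100 * acc / length(controls))
}
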