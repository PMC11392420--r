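#' Voxel volumes on a fixed grid
#'
#' A `volume_grid` is the carrier for every image in the pipeline: binary
#' lesion and grey-matter masks, probabilistic tract atlas maps, disconnectome
#' maps and statistic maps. It couples a 3D array of voxel values with the
#' voxel size (mm) and a 4x4 voxel-to-world affine transform. Voxel indices
#' are 0-based and the transform maps voxel *centres*: world = A %*% (i,j,k,1).
#'
#' @param values numeric 3D array of voxel values; must be finite.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (> 0).
#' @param transform 4x4 voxel-to-world affine. Default: diagonal scaling by
#'   `voxel_size` with zero origin.
#' @return An object of class `volume_grid` with elements `values`,
#'   `voxel_size` and `transform`.
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 4)), voxel_size = c(3, 3, 3))
#' dim(g)
#' @export
volume_grid <- function(values, voxel_size = c(1, 1, 1), transform = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("grid shape components must be >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive finite values (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("voxel values must be finite", call. = FALSE)
  if (is.null(transform)) {
    transform <- diag(c(voxel_size, 1))
  }
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)) || any(!is.finite(transform)))
    stop("`transform` must be a finite 4x4 matrix", call. = FALSE)
  structure(
    list(values = values, voxel_size = voxel_size, transform = transform),
    class = "volume_grid"
  )
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
as.array.volume_grid <- function(x, ...) x$values

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s voxels @ %s mm; values in [%g, %g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(signif(x$voxel_size, 4), collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Test whether an object is a volume_grid
#' @param x object to test.
#' @return logical scalar.
#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Volume of one voxel in mm^3
#' @param grid a [volume_grid].
#' @return numeric scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

#' Replace the values of a grid, keeping its geometry
#' @param grid a [volume_grid].
#' @param values replacement array (same shape) or vector recycled to shape.
#' @return a new [volume_grid].
#' @export
with_values <- function(grid, values) {
  if (!is.array(values)) values <- array(values, dim = dim(grid$values))
  volume_grid(values, grid$voxel_size, grid$transform)
}

#' Check two grids share one space
#'
#' Every pipeline stage refuses to mix grids from different spaces; there is
#' no implicit resampling. Two grids are compatible when shape, voxel size
#' and world transform agree within tolerance.
#'
#' @param a,b [volume_grid] objects.
#' @param tol numeric tolerance on voxel size and transform entries.
#' @return logical scalar.
#' @export
grids_compatible <- function(a, b, tol = 1e-4) {
  stopifnot(is_volume_grid(a), is_volume_grid(b))
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$transform - b$transform) <= tol)
}

stop_if_incompatible <- function(a, b, what = "grids") {
  if (!grids_compatible(a, b))
    stop(sprintf("%s are not on a common space (shape/voxel size/transform mismatch)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Validate a binary mask
#'
#' Masks (lesions, grey matter, hemispheres) must contain only 0 and 1.
#'
#' @param grid a [volume_grid].
#' @return the grid, invisibly, if valid; otherwise an error.
#' @export
assert_mask <- function(grid) {
  stopifnot(is_volume_grid(grid))
  v <- grid$values
  if (!all(v == 0 | v == 1))
    stop("mask contains values other than {0,1}", call. = FALSE)
  invisible(grid)
}

#' Mask volume in cubic centimetres
#'
#' Exactly `count * voxel volume / 1000`.
#'
#' @param mask a binary [volume_grid].
#' @return numeric scalar, cc.
#' @export
mask_volume_cc <- function(mask) {
  assert_mask(mask)
  sum(mask$values) * voxel_volume_mm3(mask) / 1000
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param grid a [volume_grid].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed (continuous voxel space).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  xyz1 <- cbind(ijk, 1) %*% t(grid$transform)
  xyz1[, 1:3, drop = FALSE]
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @param grid a [volume_grid].
#' @param xyz n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  inv <- solve(grid$transform)
  ijk1 <- cbind(xyz, 1) %*% t(inv)
  ijk1[, 1:3, drop = FALSE]
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask if `TRUE`, validate that the volume is a binary mask.
#' @return a [volume_grid].
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("not a readable NIfTI volume: %s (%s)",
                                                   path, conditionMessage(e)), call. = FALSE))
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D volume, got %d dimensions", length(dim(a))), call. = FALSE)
  a <- array(as.double(a), dim = dim(a))   # plain array, no image attributes
  g <- volume_grid(a,
                   voxel_size = RNifti::pixdim(img)[1:3],
                   transform = unclass(RNifti::xform(img))[1:4, 1:4])
  if (mask) assert_mask(g)
  g
}

#' Write a volume as NIfTI-1
#'
#' Integer-valued volumes round-trip bit-exactly through [read_volume()].
#'
#' @param grid a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_volume_grid(grid))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::`qform<-`(img, structure(grid$transform, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
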