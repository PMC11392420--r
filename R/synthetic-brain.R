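#' Generate a miniature synthetic brain
#'
#' Builds the complete anatomical substrate for a simulated lesion-behaviour
#' study: an ellipsoidal brain with a grey-matter shell, left/right homologous
#' pairs of tubular white-matter tract probability maps, and per-control
#' streamline sets jittered around each tract's centreline (the stand-in for
#' the healthy-control tractography data used to estimate disconnection).
#'
#' The default grid (32 x 38 x 32 voxels at 3 mm) is large enough to host at
#' least eight tube tracts while keeping whole-pipeline runs at seconds scale.
#' The world origin sits at the grid centre, so the sagittal midline is the
#' world plane x = 0; voxels with centre x < 0 form the left hemisphere.
#'
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param shape integer length-3 grid shape in voxels.
#' @param voxel_size voxel edge length(s) in mm (scalar or length 3).
#' @param n_tracts number of tract *families* (>= 2); each contributes a left
#'   and a right homologue, so `2 * n_tracts` maps are produced.
#' @param n_controls number of control streamline sets (>= 2; the emulated
#'   study design uses 10).
#' @param n_lines streamlines per tract per control.
#' @param tube_sigma Gaussian radius (mm) of the tract probability profile.
#' @return an object of class `synthetic_brain`: list with `grid` (empty
#'   template [volume_grid]), `tract_maps` (named list of probability
#'   volumes, names `tract<f>_left` / `tract<f>_right`), `gm_mask`,
#'   `brain_mask`, `hemi_left`, `hemi_right` (binary volumes), `controls`
#'   (list of [streamline_set]), `centrelines` (per tract map) and `params`.
#' @examples
#' b <- make_brain(seed = 1, n_tracts = 2, n_controls = 2)
#' names(b$tract_maps)
#' @export
make_brain <- function(seed, shape = c(32L, 38L, 32L), voxel_size = 3,
                       n_tracts = 6L, n_controls = 10L, n_lines = 8L,
                       tube_sigma = 4) {
  stopifnot(n_tracts >= 2L, n_controls >= 2L)
  shape <- as.integer(shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  ext <- shape * voxel_size
  semi <- ext / 2 - voxel_size          # brain ellipsoid semi-axes, mm
  if (semi[1] < 36 || semi[2] < 36 || semi[3] < 36)
    stop("grid too small to host tube tracts: increase shape or voxel size",
         call. = FALSE)

  # world origin at the grid centre; voxel centres at transform (i,j,k,1)
  transform <- diag(c(voxel_size, 1))
  transform[1:3, 4] <- -(shape - 1) / 2 * voxel_size
  template <- volume_grid(array(0, shape), voxel_size, transform)
  gw <- grid_world_coords(template)
  xyz <- gw$xyz

  r2 <- (xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 + (xyz[, 3] / semi[3])^2
  brain <- as.numeric(r2 <= 1)
  gm <- as.numeric(r2 <= 1 & sqrt(r2) >= 0.72)
  hemi_l <- as.numeric(brain == 1 & xyz[, 1] < 0)
  hemi_r <- as.numeric(brain == 1 & xyz[, 1] > 0)

  with_seed(seed, {
    # spread tract seats over a jittered candidate lattice in the left
    # hemisphere; right homologues are exact mirrors
    xc <- seq(-0.62, -0.38, length.out = 3) * semi[1]
    zc <- seq(-0.5, 0.5, length.out = max(3L, ceiling(n_tracts / 3))) * semi[3]
    cand <- as.matrix(expand.grid(x = xc, z = zc))
    if (nrow(cand) < n_tracts)
      stop("grid too small to seat the requested number of tracts", call. = FALSE)
    seats <- cand[sample.int(nrow(cand), n_tracts), , drop = FALSE]
    seats <- seats + matrix(runif(2 * n_tracts, -2, 2), ncol = 2)

    yspan <- 0.72 * semi[2]
    tt <- seq(0, 1, length.out = 25)
    centrelines <- list()
    tract_maps <- list()
    for (f in seq_len(n_tracts)) {
      ax <- runif(1, 1, 4); az <- runif(1, 1, 4); ph <- runif(1, 0, 2 * pi)
      cl <- cbind(
        x = seats[f, 1] + ax * sin(pi * tt),
        y = -yspan + 2 * yspan * tt,
        z = seats[f, 2] + az * sin(2 * pi * tt + ph)
      )
      for (side in c("left", "right")) {
        cls <- cl
        if (side == "right") cls[, 1] <- -cls[, 1]
        nm <- sprintf("tract%d_%s", f, side)
        centrelines[[nm]] <- cls
        # Gaussian tube profile, truncated at 5% so support stays compact
        vals <- numeric(prod(shape))
        near <- which(abs(xyz[, 1] - mean(range(cls[, 1]))) < 12 + max(abs(cls[, 1] - mean(range(cls[, 1])))) &
                      abs(xyz[, 3] - mean(range(cls[, 3]))) < 12 + max(abs(cls[, 3] - mean(range(cls[, 3])))))
        d <- polyline_distance(xyz[near, , drop = FALSE], cls)
        p <- exp(-d^2 / (2 * tube_sigma^2))
        p[p < 0.05] <- 0
        vals[near] <- p
        vals[brain == 0] <- 0
        tract_maps[[nm]] <- with_values(template, vals)
      }
    }

    controls <- lapply(seq_len(n_controls), function(cid) {
      lines <- list()
      for (nm in names(centrelines)) {
        cl <- centrelines[[nm]]
        for (l in seq_len(n_lines)) {
          o0 <- pmax(-4, pmin(4, rnorm(3, 0, 1.6)))
          o1 <- pmax(-4, pmin(4, rnorm(3, 0, 1.6)))
          wob <- pmax(-3, pmin(3, rnorm(3, 0, 1)))
          t01 <- seq(0, 1, length.out = nrow(cl))
          off <- outer(1 - t01, o0) + outer(t01, o1) +
                 outer(sin(pi * t01), wob)
          lines[[length(lines) + 1L]] <- cl + off
        }
      }
      streamline_set(lines, control_id = sprintf("control%02d", cid))
    })

    structure(list(
      grid = template,
      tract_maps = tract_maps,
      gm_mask = with_values(template, gm),
      brain_mask = with_values(template, brain),
      hemi_left = with_values(template, hemi_l),
      hemi_right = with_values(template, hemi_r),
      controls = controls,
      centrelines = centrelines,
      params = list(seed = seed, shape = shape, voxel_size = voxel_size,
                    n_tracts = n_tracts, n_controls = n_controls,
                    n_lines = n_lines, tube_sigma = tube_sigma, semi = semi)
    ), class = "synthetic_brain")
  })
}

#' @export
print.synthetic_brain <- function(x, ...) {
  cat(sprintf("<synthetic_brain> %s @ %g mm; %d tract maps (%d families), %d controls\n",
              paste(x$params$shape, collapse = "x"), x$params$voxel_size[1],
              length(x$tract_maps), x$params$n_tracts, length(x$controls)))
  invisible(x)
}

#' Generate a synthetic lesion mask
#'
#' Places a connected ellipsoidal lesion blob in the requested hemisphere,
#' sized by bisection so the achieved volume lands within 20% of the target.
#' The blob is the voxelisation of an intersection of convex bodies (random
#' anisotropic ellipsoid, brain ellipsoid, hemisphere half-space), which
#' keeps it 6-connected.
#'
#' @param seed integer RNG seed.
#' @param brain a [make_brain()] result.
#' @param side `"left"` or `"right"` hemisphere.
#' @param volume_cc target lesion volume in cc.
#' @return a binary [volume_grid] lesion mask.
#' @export
make_lesion <- function(seed, brain, side = c("left", "right"), volume_cc = 30) {
  side <- match.arg(side)
  stopifnot(inherits(brain, "synthetic_brain"), volume_cc > 0)
  template <- brain$grid
  hemi <- if (side == "left") brain$hemi_left$values else brain$hemi_right$values
  voxvol <- voxel_volume_mm3(template)
  target_vox <- volume_cc * 1000 / voxvol
  hemi_capacity <- sum(hemi)
  if (target_vox > hemi_capacity)
    stop(sprintf("target volume %.1f cc exceeds hemisphere capacity %.1f cc",
                 volume_cc, hemi_capacity * voxvol / 1000), call. = FALSE)

  gw <- grid_world_coords(template)
  xyz <- gw$xyz
  hemi_idx <- which(hemi == 1)

  with_seed(seed, {
    # centre drawn from the deeper part of the hemisphere
    semi <- brain$params$semi
    rr <- sqrt((xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 + (xyz[, 3] / semi[3])^2)
    deep <- hemi_idx[rr[hemi_idx] <= 0.8]
    if (!length(deep)) deep <- hemi_idx
    centre <- xyz[sample(deep, 1L), ]
    aniso <- exp(runif(3, -0.35, 0.35))
    aniso <- aniso / prod(aniso)^(1 / 3)

    d2 <- ((xyz[hemi_idx, 1] - centre[1]) / aniso[1])^2 +
          ((xyz[hemi_idx, 2] - centre[2]) / aniso[2])^2 +
          ((xyz[hemi_idx, 3] - centre[3]) / aniso[3])^2
    # the growing ellipsoid sweeps hemisphere voxels in order of scaled
    # distance; cutting at the target-count order statistic hits the target
    # voxel count exactly (well within the 20% contract)
    k <- max(1L, round(target_vox))
    cut <- sort(d2, partial = k)[k]
    sel <- hemi_idx[d2 <= cut]
    vals <- numeric(prod(dim(template$values)))
    vals[sel] <- 1
    with_values(template, vals)
  })
}
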