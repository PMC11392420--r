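# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Minimum distance from each row of `pts` (n x 3) to a polyline (m x 3).
polyline_distance <- function(pts, polyline) {
  n <- nrow(pts)
  dmin <- rep(Inf, n)
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]; b <- polyline[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, as.vector(ap %*% ab) / len2)) else rep(0, n)
    dd <- ap - outer(t, ab)
    dmin <- pmin(dmin, sqrt(rowSums(dd^2)))
  }
  dmin
}

# World coordinates (n x 3) of every voxel centre of a grid, plus the
# 0-based index matrix, cached per call site.
grid_world_coords <- function(grid) {
  shp <- dim(grid$values)
  ijk <- as.matrix(expand.grid(i = 0:(shp[1] - 1L),
                               j = 0:(shp[2] - 1L),
                               k = 0:(shp[3] - 1L)))
  list(ijk = ijk, xyz = voxel_to_world(grid, ijk))
}
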