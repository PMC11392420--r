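# Shared small fixtures, built in code once per test run.

# tiny brain: 2 tract families, 3 controls -- seconds-scale
tiny_brain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_brain(401, n_tracts = 2, n_controls = 3,
                                             n_lines = 4)
    cache
  }
})

# small normative model fitted on 80 control assessments
small_normative <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- make_normative_cohort(402, n_controls = 60, n_assessments = 80)
      cache <<- list(cohort = cohort, model = normative_fit(cohort))
    }
    cache
  }
})

# a perfect-mirroring 54-trial session (robot at the 9 targets, participant
# matching exactly), optionally perturbed by a function of the mirrored
# position
perfect_session <- function(perturb = NULL) {
  tg <- apm_targets()
  rows <- lapply(1:6, function(b) {
    mirr <- tg
    if (!is.null(perturb)) mirr <- perturb(mirr)
    data.frame(target = 1:9, block = b,
               robot_x = tg[, 1], robot_y = tg[, 2],
               match_x = -mirr[, 1], match_y = mirr[, 2])
  })
  do.call(rbind, rows)
}

# brute-force dense-sampling rasterisation oracle (0.01 mm steps)
dense_raster_oracle <- function(line, grid, step = 0.01) {
  pts <- list()
  for (s in seq_len(nrow(line) - 1L)) {
    p0 <- line[s, ]; p1 <- line[s + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / step)))
    pts[[s]] <- outer(tt, p1 - p0) + rep(p0, each = length(tt))
  }
  u <- world_to_voxel(grid, do.call(rbind, pts))
  ijk <- floor(u + 0.5)
  shp <- dim(grid$values)
  keep <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
          ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
          ijk[, 3] >= 0 & ijk[, 3] < shp[3]
  unique(ijk[keep, , drop = FALSE])
}

voxel_key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
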