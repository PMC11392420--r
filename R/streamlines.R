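#' Streamline sets
#'
#' A `streamline_set` holds the tractography substrate of one control
#' participant: a list of polylines, each an n x 3 matrix of world-mm points.
#' Ten such sets stand in for the healthy-control diffusion data from which
#' lesion-seeded disconnection is estimated.
#'
#' @param streamlines list of numeric matrices, each n x 3 with n >= 2 and
#'   all points finite.
#' @param control_id label for the control participant.
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, control_id = "control") {
  if (!is.list(streamlines) || length(streamlines) == 0L)
    stop("`streamlines` must be a non-empty list of point matrices", call. = FALSE)
  streamlines <- lapply(streamlines, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each streamline must have 3 columns (x,y,z mm)", call. = FALSE)
    if (nrow(m) < 2L) stop("each streamline must have >= 2 points", call. = FALSE)
    if (any(!is.finite(m))) stop("streamline points must be finite", call. = FALSE)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  structure(list(control_id = as.character(control_id), streamlines = streamlines),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, 1L)
  cat(sprintf("<streamline_set> '%s': %d streamlines, %d points total\n",
              x$control_id, length(x$streamlines), sum(npts)))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Write streamlines as whitespace-delimited text
#'
#' The dialect is deliberately plain so fixtures need no binary dependency:
#' one `x y z` point per line, a blank line between streamlines, `#` comment
#' lines ignored. The control id is stored in a `# control: <id>` header.
#'
#' @param set a [streamline_set].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_streamlines <- function(set, path) {
  stopifnot(inherits(set, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# control: %s", set$control_id), con)
  for (m in set$streamlines) {
    writeLines(apply(format(m, trim = TRUE, digits = 17), 1L, paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read streamlines from whitespace-delimited text
#'
#' @param path file written by [write_streamlines()] (or any file in that
#'   dialect).
#' @return a [streamline_set].
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  id <- "control"
  hdr <- grep("^#\\s*control:", lines, value = TRUE)
  if (length(hdr)) id <- trimws(sub("^#\\s*control:", "", hdr[1]))
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(c(TRUE, blank[-length(blank)]))
  pieces <- split(lines[!blank], grp[!blank])
  streamlines <- lapply(pieces, function(ls) {
    m <- do.call(rbind, lapply(strsplit(trimws(ls), "\\s+"), as.numeric))
    m
  })
  streamline_set(unname(streamlines), control_id = id)
}

#' Rasterise a polyline onto a voxel grid
#'
#' Returns every voxel whose cube any segment of the polyline enters, by exact
#' 3D traversal: in continuous voxel space (voxel centres at integer indices,
#' voxel `v` spanning `[v-0.5, v+0.5)`) each segment is cut at every
#' half-integer boundary plane it crosses and the midpoint of each cut
#' identifies the voxel traversed. Deterministic; voxels outside the grid are
#' dropped (a polyline wholly outside the grid gives an empty set).
#'
#' @param line numeric matrix n x 3 of world-mm points (n >= 1; a single
#'   point marks just the voxel containing it).
#' @param grid a [volume_grid] defining the voxel space.
#' @return integer matrix m x 3 of unique 0-based voxel indices (columns
#'   i, j, k).
#' @export
rasterize_streamline <- function(line, grid) {
  stopifnot(is_volume_grid(grid))
  line <- as.matrix(line)
  if (ncol(line) != 3L) stop("`line` must be an n x 3 matrix", call. = FALSE)
  u <- world_to_voxel(grid, line)  # continuous 0-based voxel coords
  shp <- dim(grid$values)
  pts <- list(u)                   # include vertices themselves
  if (nrow(u) >= 2L) {
    for (s in seq_len(nrow(u) - 1L)) {
      p0 <- u[s, ]; p1 <- u[s + 1L, ]
      d <- p1 - p0
      ts <- numeric(0)
      for (ax in 1:3) {
        if (d[ax] != 0) {
          lo <- min(p0[ax], p1[ax]); hi <- max(p0[ax], p1[ax])
          first <- ceiling(lo - 0.5) + 0.5
          if (first <= hi) {
            planes <- seq(first, hi, by = 1)
            planes <- planes[planes > lo & planes < hi]
            if (length(planes)) ts <- c(ts, (planes - p0[ax]) / d[ax])
          }
        }
      }
      ts <- sort(unique(c(0, ts[ts > 0 & ts < 1], 1)))
      mid <- (ts[-length(ts)] + ts[-1]) / 2
      pts[[length(pts) + 1L]] <- outer(mid, d) + rep(p0, each = length(mid))
    }
  }
  pp <- do.call(rbind, pts)
  ijk <- floor(pp + 0.5)           # nearest-integer voxel of each sample
  keep <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
          ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
          ijk[, 3] >= 0 & ijk[, 3] < shp[3]
  ijk <- ijk[keep, , drop = FALSE]
  ijk <- unique(ijk)
  storage.mode(ijk) <- "integer"
  colnames(ijk) <- c("i", "j", "k")
  ijk
}

#' Rasterise every streamline of a set to linear voxel indices
#'
#' Convenience wrapper caching the per-streamline voxel sets used by
#' visitation and disconnectome maps.
#'
#' @param set a [streamline_set].
#' @param grid a [volume_grid].
#' @return list of integer vectors of 1-based linear indices into
#'   `grid$values`, one per streamline.
#' @export
rasterize_streamline_set <- function(set, grid) {
  stopifnot(inherits(set, "streamline_set"))
  shp <- dim(grid$values)
  lapply(set$streamlines, function(m) {
    ijk <- rasterize_streamline(m, grid)
    as.integer(ijk[, 1] + shp[1] * (ijk[, 2] + shp[2] * ijk[, 3]) + 1L)
  })
}
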