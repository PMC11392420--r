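#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates cluster extent and height across thresholds so spatially
#' coherent signal is boosted without a fixed cluster-forming threshold:
#' `TFCE(v) = sum_k extent(v, h_k)^E * h_k^H * dh` over `nsteps` midpoint
#' thresholds `h_k = (k - 1/2) * dh`, `dh = max(stat)/nsteps`, with clusters
#' formed by 6-connectivity. Only the positive part of the map is enhanced
#' (one-sided contrast). Defaults E = 0.5, H = 2, 100 steps are the
#' published defaults of the method.
#'
#' For an isolated single-voxel peak of height `h` the enhancement
#' approximates `h^3/3` (the exact integral of `1^0.5 * u^2`).
#'
#' @param stat a [volume_grid] or 3D array of test statistics.
#' @param E cluster-extent exponent.
#' @param H height exponent.
#' @param nsteps number of integration steps.
#' @return enhanced map, same type as the input.
#' @export
tfce <- function(stat, E = 0.5, H = 2, nsteps = 100L) {
  g <- NULL
  if (is_volume_grid(stat)) { g <- stat; stat <- stat$values }
  stopifnot(is.array(stat), length(dim(stat)) == 3L)
  out <- tfce_enhance_cpp(as.numeric(stat), as.integer(dim(stat)),
                          E, H, as.integer(nsteps))
  out <- array(out, dim = dim(stat))
  if (!is.null(g)) with_values(g, out) else out
}

# t-statistics for the column `which` of design X, computed for every column
# of response matrix Y at once (ordinary least squares, closed form).
ols_t_multi <- function(X, Y, which) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  B[which, ] / sqrt(sigma2 * XtXi[which, which])
}

#' Voxelwise group comparison of disconnectome maps with TFCE + permutation
#'
#' At every voxel a linear model `value ~ group + covariate` is fitted and
#' the one-sided t statistic for the impaired > unimpaired contrast is
#' TFCE-enhanced. Family-wise error corrected p-values come from the
#' permutation distribution of the image-wide maximum TFCE score under
#' Freedman-Lane residual permutation: the nuisance-only model (intercept +
#' covariate) is fitted, its residuals are permuted and re-added to its
#' fitted values, and the full model is refitted on each permuted sample.
#' With no covariate this reduces to simple label permutation. The observed
#' statistic is included in its own null (add-one rule), so corrected
#' p-values lie in `{1/(n_perm+1), ..., 1}`.
#'
#' Analysis is restricted to voxels whose values vary across participants;
#' all other voxels get corrected p = 1.
#'
#' @param maps list of participant [volume_grid]s on one grid (e.g.
#'   disconnectome maps), or a participants x voxels matrix (then `grid`
#'   must be given).
#' @param impaired logical vector, one per participant; both groups must be
#'   non-empty.
#' @param covariate optional numeric nuisance covariate (grey-matter lesion
#'   volume in the emulated design); must not be constant.
#' @param grid reference [volume_grid] (taken from `maps[[1]]` when maps are
#'   volumes).
#' @param n_perm number of permutations (default 4000; fewer than 100 draws
#'   a warning).
#' @param E,H,nsteps TFCE parameters, see [tfce()].
#' @param seed RNG seed for the permutation draw.
#' @param alpha,alpha_peak significance levels for the two reported masks
#'   (corrected p < 0.05, and the stricter post-hoc peak p < 0.001).
#' @return list of class `tfce_result`: `t_map`, `tfce_map`, `p_fwe`
#'   (volumes), `sig_mask` and `peak_mask` (binary volumes at `alpha` /
#'   `alpha_peak`), `max_null` (permutation maxima), `n_perm`, `mask`.
#' @export
group_difference_tfce <- function(maps, impaired, covariate = NULL, grid = NULL,
                                  n_perm = 4000L, E = 0.5, H = 2, nsteps = 100L,
                                  seed = NULL, alpha = 0.05, alpha_peak = 0.001) {
  if (is.list(maps)) {
    grid <- maps[[1]]
    for (m in maps) stop_if_incompatible(grid, m, "participant maps")
    Y <- do.call(rbind, lapply(maps, function(m) as.numeric(m$values)))
  } else {
    stopifnot(is.matrix(maps), is_volume_grid(grid))
    Y <- maps
  }
  n <- nrow(Y)
  impaired <- as.logical(impaired)
  stopifnot(length(impaired) == n)
  if (!any(impaired) || all(impaired))
    stop("both impaired and unimpaired groups must be non-empty", call. = FALSE)
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    if (sd(covariate) == 0)
      stop("constant covariate: nuisance model cannot be fitted", call. = FALSE)
  }
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse permutation null", call. = FALSE)

  shp <- dim(grid$values)
  inmask <- which(apply(Y, 2, function(col) any(col != col[1])))
  Ym <- Y[, inmask, drop = FALSE]

  Z <- if (is.null(covariate)) matrix(1, n, 1) else cbind(1, covariate)
  X <- cbind(Z, group = as.numeric(impaired))
  gcol <- ncol(X)
  if (qr(X)$rank < ncol(X))
    stop("singular design: group is confounded with the nuisance terms", call. = FALSE)

  to_grid <- function(v_mask, fill = 0) {
    full <- rep(fill, prod(shp))
    full[inmask] <- v_mask
    with_values(grid, array(full, dim = shp))
  }

  t_obs <- ols_t_multi(X, Ym, gcol)
  tfce_obs_grid <- tfce(to_grid(t_obs), E, H, nsteps)
  tfce_obs <- as.numeric(tfce_obs_grid$values)[inmask]

  # Freedman-Lane: permute residuals of the nuisance-only model
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Yfit <- Hz %*% Ym
  Eres <- Ym - Yfit

  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(j) {
      pi <- sample.int(n)
      tj <- ols_t_multi(X, Yfit + Eres[pi, , drop = FALSE], gcol)
      max(tfce(to_grid(tj), E, H, nsteps)$values)
    }, numeric(1))
  })

  counts <- vapply(tfce_obs, function(v) sum(max_null >= v), numeric(1))
  p_mask <- (1 + counts) / (n_perm + 1)

  structure(list(
    t_map = to_grid(t_obs),
    tfce_map = tfce_obs_grid,
    p_fwe = to_grid(p_mask, fill = 1),
    sig_mask = to_grid(as.numeric(p_mask < alpha)),
    peak_mask = to_grid(as.numeric(p_mask < alpha_peak)),
    max_null = max_null,
    mask = to_grid(rep(1, length(inmask))),
    n_perm = n_perm, E = E, H = H, nsteps = nsteps
  ), class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat(sprintf("<tfce_result> %d permutations; %d voxels analysed; %d significant (FWE p<0.05), %d at peak p<0.001\n",
              x$n_perm, sum(x$mask$values), sum(x$sig_mask$values),
              sum(x$peak_mask$values)))
  invisible(x)
}
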