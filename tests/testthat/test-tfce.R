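# R-side brute-force TFCE oracle: label components with igraph at each
# midpoint threshold and accumulate extent^E * h^H * dh.
tfce_oracle <- function(a, E = 0.5, H = 2, nsteps = 100) {
  hmax <- max(a)
  out <- array(0, dim(a))
  if (hmax <= 0) return(out)
  dh <- hmax / nsteps
  shp <- dim(a)
  for (k in 1:nsteps) {
    h <- (k - 0.5) * dh
    idx <- which(a >= h)
    if (!length(idx)) next
    ar <- arrayInd(idx, shp)
    key <- paste(ar[, 1], ar[, 2], ar[, 3])
    edges <- do.call(rbind, lapply(1:3, function(ax) {
      nb <- ar; nb[, ax] <- nb[, ax] + 1L
      ok <- paste(nb[, 1], nb[, 2], nb[, 3]) %in% key
      cbind(key[ok], paste(nb[ok, 1], nb[ok, 2], nb[ok, 3]))
    }))
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(key)
    if (nrow(edges)) g <- g + igraph::edges(t(edges))
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership[key]]
    out[idx] <- out[idx] + sizes^E * h^H * dh
  }
  out
}

test_that("an isolated peak integrates to h^3/3", {
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 2
  got <- tfce(a)[5, 5, 5]
  expect_lt(abs(got - 2^3 / 3) / (2^3 / 3), 0.01)
  # two-voxel cluster of equal height: extent 2 throughout
  b <- array(0, c(9, 9, 9)); b[4:5, 5, 5] <- 1.5
  expect_lt(abs(tfce(b)[4, 5, 5] - sqrt(2) * 1.5^3 / 3) / (sqrt(2) * 1.5^3 / 3),
            0.01)
})

test_that("the compiled TFCE agrees with a connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(51)
  for (rep in 1:3) {
    a <- array(pmax(0, rnorm(6^3, 0.2, 1)), c(6, 6, 6))
    expect_equal(tfce(a, nsteps = 40), tfce_oracle(a, nsteps = 40),
                 tolerance = 1e-10)
  }
})

test_that("TFCE is monotone under a positive offset and in map order", {
  set.seed(52)
  a <- array(pmax(0, rnorm(7^3, 0, 1)), c(7, 7, 7))
  t1 <- tfce(a, nsteps = 400)
  t2 <- tfce(a + 0.5, nsteps = 400)
  expect_true(all(t2 - t1 >= -1e-6 * max(t1)))
  # all-nonpositive maps enhance to zero
  expect_true(all(tfce(array(-1, c(5, 5, 5))) == 0))
})

make_null_maps <- function(n, shp = c(7, 7, 7), seed = 1) {
  set.seed(seed)
  grid <- volume_grid(array(0, shp))
  maps <- lapply(1:n, function(i)
    with_values(grid, array(pmax(0, rnorm(prod(shp), 1, 1)), shp)))
  list(grid = grid, maps = maps)
}

test_that("voxelwise t-statistics match a normal-equations oracle", {
  nm <- make_null_maps(16, seed = 53)
  imp <- rep(c(TRUE, FALSE), 8)
  cov <- runif(16, 0, 10)
  res <- group_difference_tfce(nm$maps, imp, cov, n_perm = 100, seed = 1)
  # oracle: per-voxel lm() t for the group column
  Y <- do.call(rbind, lapply(nm$maps, function(m) as.numeric(m$values)))
  v <- which(apply(Y, 2, sd) > 0)[c(1, 10, 100, 200)]
  for (j in v) {
    fit <- summary(lm(Y[, j] ~ cov + imp))
    expect_equal(as.numeric(res$t_map$values)[j],
                 fit$coefficients["impTRUE", "t value"], tolerance = 1e-8)
  }
})

test_that("permutation p-values obey the add-one rule and its range", {
  nm <- make_null_maps(12, seed = 54)
  imp <- rep(c(TRUE, FALSE), 6)
  res <- suppressWarnings(
    group_difference_tfce(nm$maps, imp, n_perm = 99, seed = 2))
  p <- as.numeric(res$p_fwe$values)[res$mask$values == 1]
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_true(all(abs(p * 100 - round(p * 100)) < 1e-9))
  expect_warning(group_difference_tfce(nm$maps, imp, n_perm = 50, seed = 2),
                 "coarse")
})

test_that("Freedman-Lane with a vanishing covariate matches label permutation", {
  nm <- make_null_maps(14, seed = 55)
  imp <- rep(c(TRUE, FALSE), 7)
  tiny <- rnorm(14, 0, 0.01)
  r0 <- group_difference_tfce(nm$maps, imp, covariate = NULL,
                              n_perm = 400, seed = 3)
  r1 <- group_difference_tfce(nm$maps, imp, covariate = tiny,
                              n_perm = 400, seed = 3)
  p0 <- as.numeric(r0$p_fwe$values); p1 <- as.numeric(r1$p_fwe$values)
  expect_lt(mean(abs(p0 - p1)), 0.02)   # Monte-Carlo agreement
  expect_lt(max(abs(p0 - p1)), 0.1)
  expect_gt(cor(p0, p1), 0.99)
})

test_that("input validation catches degenerate group and covariate settings", {
  nm <- make_null_maps(8, seed = 56)
  expect_error(group_difference_tfce(nm$maps, rep(TRUE, 8), n_perm = 100),
               "non-empty")
  expect_error(group_difference_tfce(nm$maps, rep(c(TRUE, FALSE), 4),
                                     covariate = rep(1, 8), n_perm = 100),
               "constant covariate")
})

test_that("a strong localised group effect is detected over most of its extent", {
  set.seed(57)
  shp <- c(10, 10, 10)
  grid <- volume_grid(array(0, shp))
  effect_vox <- as.matrix(expand.grid(3:6, 4:6, 4:6))  # 36-voxel block
  n <- 60
  imp <- rep(c(TRUE, FALSE), n / 2)
  maps <- lapply(1:n, function(i) {
    v <- array(pmax(0, rnorm(prod(shp), 1, 1)), shp)
    if (imp[i]) v[effect_vox] <- v[effect_vox] + 3
    with_values(grid, v)
  })
  res <- group_difference_tfce(maps, imp, n_perm = 300, seed = 4)
  hit <- mean(res$sig_mask$values[effect_vox] == 1)
  expect_gte(hit, 0.8)
})
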