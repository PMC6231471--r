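test_that("trend surface equals direct polynomial expansion", {
  set.seed(1)
  coords <- cbind(x = runif(5, 100, 110), y = runif(5, 30, 40))
  ts <- trend_surface(coords)
  xc <- coords[, 1] - mean(coords[, 1])
  yc <- coords[, 2] - mean(coords[, 2])
  oracle <- cbind(x = xc, y = yc, xy = xc * yc, x2 = xc^2, y2 = yc^2)
  expect_equal(unname(ts), unname(oracle))
  expect_equal(sum(ts[, "x"]), 0, tolerance = 1e-10)
  expect_equal(sum(ts[, "y"]), 0, tolerance = 1e-10)

  # vertical line: x-derived columns dropped, y terms retained
  vert <- cbind(x = rep(105, 4), y = c(30, 32, 34, 36))
  expect_warning(tv <- trend_surface(vert), "degenerate")
  expect_false(any(c("x", "xy", "x2") %in% colnames(tv)))
  expect_true(all(c("y", "y2") %in% colnames(tv)))
  expect_error(trend_surface(coords[1:2, ]), "three")
})

test_that("PCA reduction honors its criteria and matches a dense solver", {
  set.seed(2)
  # rank-1 + tiny noise: one axis reaches 75% cumulative variance
  u <- rnorm(10)
  M1 <- outer(u, rnorm(5)) + matrix(rnorm(50, sd = 0.01), 10)
  r1 <- pca_reduce(M1, "cum_var", cum_var = 0.75)
  expect_equal(ncol(r1$scores), 1)

  # isotropic: eigenvalue > 1 retains nothing -> falls back to PC1
  M2 <- matrix(rnorm(400), 100, 4)
  r2 <- pca_reduce(M2, "eigenvalue")
  expect_gte(ncol(r2$scores), 1)

  # 14-variable table: eigenvalues match dense eigendecomposition
  M3 <- matrix(rnorm(17 * 14), 17, 14) %*% diag(seq(1, 3, length = 14))
  r3 <- pca_reduce(M3, "fixed", k = 3)
  ev <- eigen(stats::cor(M3), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(r3$eigenvalues, ev, tolerance = 1e-8)
  M4 <- cbind(M3, const = 1)
  expect_warning(pca_reduce(M4, "fixed", k = 2), "constant")
})

test_that("Ezekiel adjustment has its closed forms and guards", {
  expect_equal(adjusted_r2(0.5, 17, 2), 1 - 0.5 * 16 / 14)
  expect_equal(adjusted_r2(1, 10, 3), 1)
  expect_equal(adjusted_r2(0.37, 10, 0), 0.37)
  expect_error(adjusted_r2(0.5, 4, 3), "undefined")
})

test_that("RDA matches eigen identities and the vegan adjusted R2", {
  set.seed(3)
  F <- matrix(rnorm(17 * 40), 17, 40)
  Fc <- scale(F, scale = FALSE)
  # X = leading PC scores of F -> R2 equals that PC's variance share
  pc <- prcomp(Fc)
  r <- rda_freqs(F, pc$x[, 1, drop = FALSE])
  expect_equal(r$r2, pc$sdev[1]^2 / sum(pc$sdev^2), tolerance = 1e-8)

  # X orthogonal to all variation in F: residual direction of noise
  set.seed(4)
  Xr <- matrix(rnorm(17), 17, 1)
  Xo <- Xr - Fc %*% solve(crossprod(Fc) + diag(1e-8, 40),
                          crossprod(Fc, Xr))
  # build F with strictly fewer dimensions so an orthogonal X exists
  F2 <- matrix(rnorm(17 * 3), 17, 3) %*% matrix(rnorm(3 * 40), 3, 40)
  F2c <- scale(F2, scale = FALSE)
  q <- qr(cbind(F2c))
  basis <- qr.Q(q)[, seq_len(qr(F2c)$rank)]
  X2 <- rnorm(17)
  X2 <- X2 - basis %*% crossprod(basis, X2)
  r2 <- rda_freqs(F2, matrix(X2))
  expect_lt(r2$r2, 1e-8)
  expect_lte(r2$adj_r2, 0)

  # self-conditioning: partial R2 is zero
  X <- matrix(rnorm(17 * 2), 17, 2)
  rp <- rda_freqs(F, X, Z = X)
  expect_lt(rp$r2, 1e-8)

  # adjusted R2 agrees with Ezekiel and with vegan's own report
  r3 <- rda_freqs(F, X)
  expect_equal(r3$adj_r2, adjusted_r2(r3$r2, 17, 2), tolerance = 1e-10)
  expect_error(rda_freqs(F, matrix(rnorm(17 * 17), 17)), "fewer")
})

test_that("permutation tests hit the extreme and reproducible cases", {
  set.seed(5)
  X <- matrix(rnorm(12 * 2), 12, 2)
  F <- X %*% matrix(rnorm(2 * 20), 2, 20)  # perfect dependence
  pt <- permutation_test(F, X, n_perm = 199, seed = 1)
  expect_equal(pt$p, 1 / 200)
  pt2 <- permutation_test(F, X, n_perm = 199, seed = 1)
  expect_identical(pt$p, pt2$p)
})

test_that("forward selection keeps signal and rejects noise", {
  set.seed(6)
  y <- rnorm(14)
  F <- outer(y, rnorm(30)) + matrix(rnorm(14 * 30, sd = 0.4), 14)
  x <- rnorm(14)
  sel <- forward_select(F, cbind(x = x, y = y), alpha = 0.05,
                        n_perm = 199, seed = 2)
  expect_true("y" %in% sel)
  expect_false("x" %in% sel)

  # pure-noise candidates: empty selection in >= 95% of runs
  set.seed(7)
  empty <- replicate(100, {
    Fn <- matrix(rnorm(10 * 15), 10, 15)
    cand <- matrix(rnorm(10 * 3), 10, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
    length(forward_select(Fn, cand, alpha = 0.05, n_perm = 99,
                          seed = sample.int(1e6, 1))) == 0
  })
  expect_gte(mean(empty), 0.95)
})

test_that("the fraction ledger reproduces the published subtraction arithmetic", {
  led <- fraction_ledger(0.354, 0.150, 0.358)
  expect_equal(led$env_given_geog, 0.208, tolerance = 1e-12)
  expect_equal(led$geog_given_env, 0.004, tolerance = 1e-12)
  expect_equal(led$joint, 0.146, tolerance = 1e-12)
  expect_equal(led$total_explained, 0.358)
  expect_equal(led$total_unexplained, 0.642)
  # identity: individual + joint = total (exact)
  expect_equal(led$env_given_geog + led$geog_given_env + led$joint,
               led$total_explained, tolerance = 1e-12)
})

test_that("variance partition handles confounded and orthogonal designs", {
  set.seed(8)
  n <- 16
  env <- matrix(rnorm(n * 2), n, 2)
  # fully confounded: identical matrices
  F <- env %*% matrix(rnorm(2 * 30), 2, 30) +
    matrix(rnorm(n * 30, sd = 0.5), n)
  vp <- variance_partition(F, env, env, n_perm = 99, seed = 1)
  tab <- vp$table
  expect_lt(abs(tab$adj_r2[tab$fraction == "F~env.|geog."]), 1e-8)
  expect_lt(abs(tab$adj_r2[tab$fraction == "F~geog.|env."]), 1e-8)
  expect_equal(tab$adj_r2[tab$fraction == "F~env.+geog."],
               tab$adj_r2[tab$fraction == "F~env."], tolerance = 1e-8)
  # ledger identity at full precision
  led <- vp$ledger
  expect_equal(led$env_given_geog + led$geog_given_env + led$joint,
               led$total_explained, tolerance = 1e-12)
  expect_equal(led$total_explained + led$total_unexplained, 1)

  # orthogonal designs: joint ~ 0 (up to the small-sample curvature of
  # the Ezekiel adjustment) and fractions additive
  geo <- matrix(rnorm(n * 2), n, 2)
  geo <- geo - env %*% solve(crossprod(env), crossprod(env, geo))
  F2 <- env %*% matrix(rnorm(2 * 30), 2, 30) +
    geo %*% matrix(rnorm(2 * 30), 2, 30) +
    matrix(rnorm(n * 30, sd = 0.3), n)
  vp2 <- variance_partition(F2, env, geo, n_perm = 99, seed = 2)
  expect_lt(abs(vp2$ledger$joint), 0.15)
})

test_that("partition agrees with vegan's variance partitioning", {
  set.seed(9)
  n <- 15
  F <- matrix(rnorm(n * 25), n, 25)
  env <- matrix(rnorm(n * 2), n, 2)
  geo <- matrix(rnorm(n), n, 1)
  vp <- variance_partition(F, env, geo, n_perm = 99, seed = 3)
  ref <- vegan::varpart(scale(F, scale = FALSE), env, geo)
  fr <- ref$part$indfract$Adj.R.square
  expect_equal(vp$ledger$env_given_geog, fr[1], tolerance = 1e-8)   # [a]
  expect_equal(vp$ledger$geog_given_env, fr[2], tolerance = 1e-8)   # [b]
  expect_equal(vp$ledger$joint, fr[3], tolerance = 1e-8)            # [c]
  expect_equal(vp$ledger$total_unexplained, fr[4], tolerance = 1e-8)
})

test_that("mitotype constraints drop singletons and reduce to PCs", {
  set.seed(10)
  pops <- rep(paste0("P", 1:6), each = 8)
  ind <- paste0("i", seq_along(pops))
  mito <- sample(paste0("M", 1:4), length(pops), replace = TRUE)
  mito[1] <- "RARE"   # singleton
  names(mito) <- ind
  popmap <- stats::setNames(pops, ind)
  mc <- mito_constraints(mito, popmap)
  expect_false("RARE" %in% colnames(mc$freq))
  expect_equal(nrow(mc$scores), 6)
  expect_gte(mc$cum_var_explained, 0.75)
})
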