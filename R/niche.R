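#' Niche sample: occurrence and background points with environments
#'
#' @param occ data frame of occurrence points: columns x, y then
#'   environmental variables.
#' @param bg data frame of background points, same columns.
#' @param group group label.
#' @return a \code{niche_sample} object.
#' @export
niche_sample <- function(occ, bg, group = "group") {
  occ <- as.data.frame(occ)
  bg <- as.data.frame(bg)
  if (!identical(colnames(occ), colnames(bg)))
    stop("occurrence and background tables must share columns")
  if (nrow(occ) < 4)
    stop("need at least 4 occurrence points (resampling keeps >= 3)")
  structure(list(occ = occ, bg = bg, group = group,
                 env_cols = setdiff(colnames(occ), c("x", "y"))),
            class = "niche_sample")
}

#' @export
print.niche_sample <- function(x, ...) {
  cat(sprintf("niche_sample '%s': %d occurrences, %d background points, %d variables\n",
              x$group, nrow(x$occ), nrow(x$bg), length(x$env_cols)))
  invisible(x)
}

#' Reduce environmental space to independent niche axes
#'
#' Correlation-matrix PCA of the pooled occurrence and background
#' environments of all supplied samples; axes with eigenvalue > 1 are
#' retained (at least one). Constant variables are dropped with a
#' warning.
#'
#' @param samples list of \code{\link{niche_sample}} objects.
#' @return list with \code{loadings}, \code{eigenvalues}, \code{center},
#'   \code{scale}, retained axis count \code{n_axes}, per-axis variance
#'   share and top-loading variables.
#' @export
niche_axes <- function(samples) {
  if (inherits(samples, "niche_sample")) samples <- list(samples)
  env <- do.call(rbind, lapply(samples, function(s)
    rbind(s$occ[, s$env_cols, drop = FALSE],
          s$bg[, s$env_cols, drop = FALSE])))
  keep <- vapply(env, function(col) stats::sd(col) > 1e-12, logical(1))
  if (!all(keep)) {
    warning("dropping constant variables: ",
            paste(names(env)[!keep], collapse = ", "))
    env <- env[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  n_axes <- max(1L, sum(eig > 1))
  top <- apply(pc$rotation[, seq_len(n_axes), drop = FALSE], 2,
               function(l) names(sort(abs(l), decreasing = TRUE))[1:2])
  list(loadings = pc$rotation[, seq_len(n_axes), drop = FALSE],
       eigenvalues = eig, center = pc$center, scale = pc$scale,
       n_axes = n_axes, var_explained = eig[seq_len(n_axes)] / sum(eig),
       top_loadings = top)
}

project_env <- function(df, axes) {
  vars <- rownames(axes$loadings)
  X <- scale(as.matrix(df[, vars, drop = FALSE]),
             center = axes$center[vars], scale = axes$scale[vars])
  X %*% axes$loadings
}

#' Per-axis niche vs background divergence test
#'
#' On each reduced niche axis: the observed niche divergence dn is the
#' absolute difference between mean scores of random 75 percent subsamples
#' of the two groups' occurrences, and the background divergence db the
#' same quantity on subsamples of their background points, both over
#' \code{n_resample} draws. Divergence on an axis is supported when the
#' mean dn lies above the 95 percent null interval of db and dn itself is
#' significant by a permutation t test; conservatism when dn falls below
#' the interval; otherwise the verdict is inconclusive.
#'
#' @param A,B \code{\link{niche_sample}} objects.
#' @param axes reduced axes from \code{\link{niche_axes}}.
#' @param n_resample resampling draws.
#' @param frac subsample fraction.
#' @param n_perm permutations for the t test.
#' @param alpha significance threshold for dn.
#' @param seed integer seed.
#' @return data frame, one row per axis: dn mean, db interval, p, verdict,
#'   top loadings, variance explained.
#' @export
dn_db_test <- function(A, B, axes, n_resample = 1000, frac = 0.75,
                       n_perm = 999, alpha = 0.05, seed = 1) {
  stopifnot(inherits(A, "niche_sample"), inherits(B, "niche_sample"))
  if (nrow(A$bg) < 100 || nrow(B$bg) < 100)
    stop("need at least 100 background points per group")
  sa <- project_env(A$occ, axes)
  sb <- project_env(B$occ, axes)
  ba <- project_env(A$bg, axes)
  bb <- project_env(B$bg, axes)
  set.seed(seed)
  out <- NULL
  for (ax in seq_len(ncol(sa))) {
    if (stats::sd(c(sa[, ax], sb[, ax], ba[, ax], bb[, ax])) < 1e-12) {
      out <- rbind(out, data.frame(
        axis = ax, dn = NA, db_lo = NA, db_hi = NA, p = NA,
        verdict = "skipped (degenerate axis)",
        top_loadings = paste(axes$top_loadings[, ax], collapse = ","),
        var_explained = axes$var_explained[ax]))
      next
    }
    na <- max(3, round(frac * nrow(sa)))
    nb <- max(3, round(frac * nrow(sb)))
    ka <- max(3, round(frac * nrow(ba)))
    kb <- max(3, round(frac * nrow(bb)))
    dn_r <- replicate(n_resample,
      abs(mean(sa[sample(nrow(sa), na), ax]) -
          mean(sb[sample(nrow(sb), nb), ax])))
    db_r <- replicate(n_resample,
      abs(mean(ba[sample(nrow(ba), ka), ax]) -
          mean(bb[sample(nrow(bb), kb), ax])))
    db_int <- stats::quantile(db_r, c(0.025, 0.975), names = FALSE)
    p <- perm_t_test(sa[, ax], sb[, ax], n_perm = n_perm,
                     seed = seed + ax)
    dn_mean <- mean(dn_r)
    verdict <- if (dn_mean > db_int[2] && p < alpha) "divergence"
               else if (dn_mean < db_int[1]) "conservatism"
               else "inconclusive"
    out <- rbind(out, data.frame(
      axis = ax, dn = dn_mean, db_lo = db_int[1], db_hi = db_int[2],
      p = p, verdict = verdict,
      top_loadings = paste(axes$top_loadings[, ax], collapse = ","),
      var_explained = axes$var_explained[ax]))
  }
  rownames(out) <- NULL
  out
}

#' Permutation t test
#'
#' Two-sided Monte-Carlo permutation test of a mean difference:
#' p = (1 + number of |t_perm| >= |t_obs|) / (1 + n_perm). Returns 1 when
#' all values are identical.
#'
#' @param a,b numeric score vectors.
#' @param n_perm number of label permutations (Monte-Carlo mode).
#' @param exact enumerate all label assignments instead of sampling
#'   (feasible for small samples); the p-value is then the exact
#'   proportion of assignments at least as extreme as the observed one.
#' @param seed integer seed.
#' @return p-value.
#' @export
perm_t_test <- function(a, b, n_perm = 999, exact = FALSE, seed = 1) {
  if (length(a) == 0 || length(b) == 0) stop("empty input")
  pooled <- c(a, b)
  if (stats::sd(pooled) < 1e-15) return(1)
  if (exact) {
    if (choose(length(pooled), length(a)) > 2e5)
      stop("too many label assignments for exact enumeration")
    tstat <- function(x, y) {
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
      if (!is.finite(sp) || sp < 1e-15) sp <- 1e-15
      (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
    }
    t_obs <- abs(tstat(a, b))
    splits <- utils::combn(length(pooled), length(a))
    ts <- apply(splits, 2, function(idx)
      abs(tstat(pooled[idx], pooled[-idx])))
    return(mean(ts >= t_obs - 1e-12))
  }
  tstat <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
    if (sp < 1e-15) sp <- 1e-15
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  t_obs <- abs(tstat(a, b))
  n1 <- length(a)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pooled), n1)
    if (abs(tstat(pooled[idx], pooled[-idx])) >= t_obs - 1e-12)
      hits <- hits + 1
  }
  (1 + hits) / (1 + n_perm)
}

normalize_grid <- function(g) {
  g <- as.matrix(g)
  if (any(g < 0)) stop("suitability grids must be non-negative")
  s <- sum(g)
  if (s <= 0) stop("all-zero suitability grid")
  g / s
}

#' Schoener's D niche overlap
#'
#' D = 1 - 0.5 sum |p - q| over the normalized suitability grids.
#'
#' @param P,Q suitability grids (matrices) of equal shape.
#' @return D in [0, 1].
#' @export
schoener_d <- function(P, Q) {
  P <- normalize_grid(P)
  Q <- normalize_grid(Q)
  if (!all(dim(P) == dim(Q))) stop("grid shapes differ")
  1 - 0.5 * sum(abs(P - Q))
}

#' Warren's I niche overlap
#'
#' I = 1 - 0.5 sum (sqrt p - sqrt q)^2 (one minus squared Hellinger
#' distance) over the normalized suitability grids.
#'
#' @param P,Q suitability grids (matrices) of equal shape.
#' @return I in [0, 1].
#' @export
warren_i <- function(P, Q) {
  P <- normalize_grid(P)
  Q <- normalize_grid(Q)
  if (!all(dim(P) == dim(Q))) stop("grid shapes differ")
  1 - 0.5 * sum((sqrt(P) - sqrt(Q))^2)
}

#' Kernel-density suitability surface
#'
#' Normalized two-dimensional kernel density of occurrence coordinates on
#' a fixed grid: the pluggable stand-in suitability model used by the
#' background test (externally produced suitability rasters can be used
#' in its place, the overlap statistics are model-agnostic).
#'
#' @param points data frame with columns x, y.
#' @param grid_shape c(nx, ny) grid resolution.
#' @param lims c(xmin, xmax, ymin, ymax); defaults to the point extent
#'   padded by 10 percent.
#' @return normalized suitability matrix with attribute \code{lims}.
#' @export
kde_suitability <- function(points, grid_shape = c(50, 50), lims = NULL) {
  x <- points$x
  y <- points$y
  if (is.null(lims)) {
    padx <- 0.1 * max(diff(range(x)), 1e-6)
    pady <- 0.1 * max(diff(range(y)), 1e-6)
    lims <- c(range(x) + c(-padx, padx), range(y) + c(-pady, pady))
  }
  bw <- c(max(MASS::bandwidth.nrd(x), 1e-6),
          max(MASS::bandwidth.nrd(y), 1e-6))
  kd <- MASS::kde2d(x, y, h = bw, n = grid_shape, lims = lims)
  out <- normalize_grid(kd$z)
  attr(out, "lims") <- lims
  out
}

#' Suitability-based background test of niche divergence
#'
#' Compares the observed niche overlap between two groups with a null of
#' pseudo-niches: in each replicate, as many pseudo-occurrences as the
#' focal group has are drawn from the sister group's background, a
#' suitability model is fitted to them, and its overlap (Schoener's D and
#' Warren's I) with the focal model is recorded. Observed overlap below
#' the null 5th percentile indicates divergence, above the 95th
#' conservatism.
#'
#' @param occ_A focal group occurrence points (data frame with x, y).
#' @param bg_B sister group background points.
#' @param observed_overlap named vector c(D = , I = ) of the observed
#'   overlap between the two groups' suitability models.
#' @param model suitability model function(points) -> grid; defaults to
#'   \code{\link{kde_suitability}} on a shared extent.
#' @param n_reps number of random samplings.
#' @param seed integer seed.
#' @return list with the null distributions, verdicts per statistic and
#'   the number of failed replicates.
#' @export
background_test <- function(occ_A, bg_B, observed_overlap,
                            model = NULL, n_reps = 100, seed = 1) {
  if (nrow(bg_B) < nrow(occ_A))
    stop("sister background must hold at least as many points as the focal occurrences")
  lims <- c(range(c(occ_A$x, bg_B$x)), range(c(occ_A$y, bg_B$y)))
  lims <- lims + c(-1, 1, -1, 1) * 0.05 * c(rep(diff(lims[1:2]) + 1e-6, 2),
                                            rep(diff(lims[3:4]) + 1e-6, 2))
  if (is.null(model))
    model <- function(pts) kde_suitability(pts, lims = lims)
  focal <- model(occ_A)
  set.seed(seed)
  nullD <- nullI <- numeric(0)
  failed <- 0
  for (r in seq_len(n_reps)) {
    idx <- sample(nrow(bg_B), nrow(occ_A))
    pseudo <- tryCatch(model(bg_B[idx, , drop = FALSE]),
                       error = function(e) NULL)
    if (is.null(pseudo)) { failed <- failed + 1; next }
    nullD <- c(nullD, schoener_d(focal, pseudo))
    nullI <- c(nullI, warren_i(focal, pseudo))
  }
  verdict <- function(obs, null) {
    qs <- stats::quantile(null, c(0.05, 0.95), names = FALSE)
    if (obs < qs[1]) "divergence"
    else if (obs > qs[2]) "conservatism"
    else "background-equivalent"
  }
  list(null_D = nullD, null_I = nullI,
       observed = observed_overlap,
       verdict_D = verdict(observed_overlap[["D"]], nullD),
       verdict_I = verdict(observed_overlap[["I"]], nullI),
       n_failed = failed)
}

#' Spearman correlations between niche axes and geographic variables
#'
#' Reported alongside the divergence table; permutation p-values.
#'
#' @param samples list of \code{\link{niche_sample}} objects.
#' @param axes reduced axes from \code{\link{niche_axes}}.
#' @param geo_vars character vector of geographic columns present in the
#'   tables (default x, y).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return data frame: axis, variable, rho, p.
#' @export
axis_geography_cor <- function(samples, axes, geo_vars = c("x", "y"),
                               n_perm = 999, seed = 1) {
  if (inherits(samples, "niche_sample")) samples <- list(samples)
  pts <- do.call(rbind, lapply(samples, function(s) s$occ))
  sc <- project_env(pts, axes)
  set.seed(seed)
  out <- NULL
  for (ax in seq_len(ncol(sc)))
    for (v in geo_vars) {
      rho <- stats::cor(sc[, ax], pts[[v]], method = "spearman")
      null <- replicate(n_perm,
        stats::cor(sc[, ax], sample(pts[[v]]), method = "spearman"))
      p <- (1 + sum(abs(null) >= abs(rho))) / (1 + n_perm)
      out <- rbind(out, data.frame(axis = ax, variable = v, rho = rho,
                                   p = p))
    }
  out
}
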