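#' PCA of a genotype matrix
#'
#' Individuals x loci principal component analysis with the standard
#' population-genetic scaling: each locus is centered at twice its allele
#' frequency and scaled by sqrt(p(1-p)); missing dosages are mean-imputed
#' for the decomposition only.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param n_axes number of axes to return (default all).
#' @return list with \code{scores} (individuals x axes), \code{loadings}
#'   (loci x axes), \code{eigenvalues}, \code{d} (singular values) and
#'   \code{scaled} (the scaled genotype matrix used).
#' @export
pca_structure <- function(G, n_axes = NULL) {
  calls <- G$calls
  if (nrow(calls) < 2 || ncol(calls) < 2)
    stop("need at least two individuals and two loci")
  p <- colMeans(calls, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("genotype matrix is constant; PCA undefined")
  X <- sweep(calls[, keep, drop = FALSE], 2, 2 * p[keep])
  X <- sweep(X, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  X[is.na(X)] <- 0
  sv <- svd(X)
  k <- min(n_axes %||% length(sv$d), length(sv$d))
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k)
  rownames(scores) <- G$individual_ids
  loadings <- matrix(0, ncol(calls), k,
                     dimnames = list(G$locus_ids, NULL))
  loadings[keep, ] <- sv$v[, 1:k, drop = FALSE]
  list(scores = scores, loadings = loadings,
       eigenvalues = sv$d^2 / (nrow(X) - 1), d = sv$d,
       scaled = X, kept_loci = keep)
}

#' Choose the number of PCs by Cattell's graphical rule
#'
#' Automated scree criterion: K is the last axis whose eigenvalue drop is
#' still at least \code{frac} of the largest drop (beyond it the scree
#' flattens).
#'
#' @param eigenvalues decreasing eigenvalue vector.
#' @param frac flatness threshold as a fraction of the largest drop.
#' @return integer K >= 1.
#' @export
cattell_k <- function(eigenvalues, frac = 0.1) {
  drops <- -diff(eigenvalues)
  if (length(drops) == 0) return(1L)
  max(1L, max(which(drops >= frac * max(drops))))
}

#' PCA-based outlier scan
#'
#' Scans SNPs for excessive association with population structure:
#' per-SNP z-scores from the multiple regression of scaled genotypes on K
#' principal component scores are combined into a Mahalanobis statistic
#' (robust covariance), rescaled by the genomic inflation factor
#' (median chi-square method), converted to p-values on K degrees of
#' freedom, and to Storey q-values.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param K number of PCs retained (e.g. from \code{\link{cattell_k}}).
#' @param fdr q-value significance threshold carried in the result.
#' @return a \code{pca_scan} object: data frame fields \code{stat}
#'   (Mahalanobis), \code{p}, \code{q}, plus \code{K}, \code{gif},
#'   \code{loadings} and the significant locus ids.
#' @export
pcadapt_scan <- function(G, K, fdr = 0.05) {
  if (K < 1) stop("K must be >= 1")
  if (K >= min(dim(G$calls))) stop("K must be below min(n_ind, n_loci)")
  pca <- pca_structure(G, K)
  X <- pca$scaled                       # n x L' (kept loci)
  d <- pca$d[1:K]
  SC <- crossprod(pca$scores[, 1:K, drop = FALSE], X)   # K x L'
  # scores are orthogonal, so the K regressions separate per axis
  rss <- colSums(X^2) - colSums(SC^2 / d^2)
  df <- nrow(X) - K - 1
  sigma2 <- pmax(rss / df, .Machine$double.eps)
  z <- SC / d / rep(sqrt(sigma2), each = K)
  Z <- t(z)                             # loci x K
  # robust center (medians) with shrinkage-regularized covariance: stays
  # calibrated under the null while damping leverage of true outliers
  ctr <- apply(Z, 2, stats::median)
  S <- stats::cov(Z)
  lambda <- 0.05
  S <- (1 - lambda) * S + lambda * diag(diag(S), ncol(Z))
  stat <- stats::mahalanobis(Z, ctr, S)
  gif <- stats::median(stat) / stats::qchisq(0.5, K)
  p <- stats::pchisq(stat / gif, df = K, lower.tail = FALSE)
  full_stat <- rep(NA_real_, ncol(G$calls))
  full_stat[pca$kept_loci] <- stat
  full_p <- rep(1, ncol(G$calls))       # constant loci carry no signal
  full_p[pca$kept_loci] <- p
  qv <- qvalues(full_p, fdr = fdr)
  structure(list(locus_id = G$locus_ids, stat = full_stat, p = full_p,
                 q = qv$q, K = K, gif = gif, fdr = fdr,
                 loadings = pca$loadings,
                 significant = G$locus_ids[qv$significant]),
            class = "pca_scan")
}

#' @export
print.pca_scan <- function(x, ...) {
  cat(sprintf("pca_scan: K = %d, GIF = %.2f, %d / %d loci significant at q <= %g\n",
              x$K, x$gif, length(x$significant), length(x$locus_id),
              x$fdr))
  invisible(x)
}

#' Storey q-values
#'
#' False discovery rate q-values with the proportion of true nulls pi0
#' estimated by the smoother method (a cubic smoothing spline through
#' pi0(lambda) evaluated at the largest lambda); falls back to pi0 = 1
#' (Benjamini-Hochberg behaviour) when the estimate is unstable.
#'
#' @param pvals p-values in [0, 1].
#' @param fdr significance threshold on q.
#' @return list with \code{q}, \code{pi0} and logical \code{significant}.
#' @export
qvalues <- function(pvals, fdr = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  lambda <- seq(0.05, 0.9, by = 0.05)
  pi0l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) 1)
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  pi0 <- min(pi0, 1)
  o <- order(pvals)
  ranked <- pi0 * m * pvals[o] / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(ranked, 1)
  list(q = q, pi0 = pi0, significant = q <= fdr)
}

#' Among-population covariance of standardized allele frequencies
#'
#' The neutral null for the environmental association scan: per locus,
#' population frequencies are centered at the across-population mean and
#' scaled by sqrt(pbar(1-pbar)); the covariance of the standardized
#' vectors is averaged over loci. A small diagonal jitter keeps the matrix
#' positive definite.
#'
#' @param freqs a \code{pop_freqs} object or a populations x loci
#'   frequency matrix.
#' @return symmetric positive-definite matrix (pops x pops).
#' @export
neutral_covariance <- function(freqs) {
  f <- if (inherits(freqs, "pop_freqs")) freqs$freq else as.matrix(freqs)
  if (nrow(f) < 2) stop("need at least two populations")
  pbar <- colMeans(f, na.rm = TRUE)
  keep <- is.finite(pbar) & pbar > 0 & pbar < 1
  if (sum(keep) < 2) stop("need at least two polymorphic loci")
  X <- sweep(f[, keep, drop = FALSE], 2, pbar[keep])
  X <- sweep(X, 2, sqrt(pbar[keep] * (1 - pbar[keep])), "/")
  X[is.na(X)] <- 0
  omega <- tcrossprod(X) / sum(keep)
  omega <- (omega + t(omega)) / 2
  omega + diag(1e-8 * mean(diag(omega)) + 1e-12, nrow(omega))
}

#' Environmental association scan against a population-covariance null
#'
#' For each SNP and environmental variable, contrasts a linear effect of
#' the standardized environment on standardized population allele
#' frequencies against the no-effect null, both with residual covariance
#' Omega. The Bayes factor integrates the effect size over a fixed grid
#' with a standard-normal prior (deterministic numerical integration in
#' place of MCMC). The nonparametric support statistic is the Spearman
#' correlation between Omega-whitened frequencies and the whitened
#' environment, averaged over \code{n_runs} random tie-breaking seeds.
#'
#' @param freqs \code{pop_freqs} or populations x loci matrix.
#' @param env_vars populations x variables matrix (standardized
#'   internally).
#' @param omega covariance from \code{\link{neutral_covariance}}.
#' @param n_runs random tie-breaking replicates averaged for rho.
#' @param seed integer seed.
#' @param beta_grid grid of standardized effect sizes integrated over.
#' @return an \code{env_assoc} object: \code{bf} and \code{rho} matrices
#'   (loci x variables) and the null covariance.
#' @export
env_assoc_scan <- function(freqs, env_vars, omega, n_runs = 5, seed = 1,
                           beta_grid = seq(-3, 3, length.out = 61)) {
  f <- if (inherits(freqs, "pop_freqs")) freqs$freq else as.matrix(freqs)
  env_vars <- as.matrix(env_vars)
  if (nrow(env_vars) != nrow(f))
    stop("environment matrix rows must match populations")
  if (!is.null(rownames(env_vars)) && !is.null(rownames(f))) {
    if (!setequal(rownames(env_vars), rownames(f)))
      stop("environment and frequency matrices name different populations")
    env_vars <- env_vars[rownames(f), , drop = FALSE]
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("omega is not positive definite")
  P <- nrow(f)
  E <- scale(env_vars)
  pbar <- colMeans(f, na.rm = TRUE)
  keep <- is.finite(pbar) & pbar > 0 & pbar < 1
  Y <- matrix(0, P, ncol(f))
  Y[, keep] <- sweep(
    sweep(f[, keep, drop = FALSE], 2, pbar[keep]), 2,
    sqrt(pbar[keep] * (1 - pbar[keep])), "/")
  Y[is.na(Y)] <- 0
  U <- chol(omega)
  Yw <- backsolve(U, Y, transpose = TRUE)
  Ew <- backsolve(U, E, transpose = TRUE)
  prior <- stats::dnorm(beta_grid)
  prior <- prior / sum(prior)
  L <- ncol(f)
  V <- ncol(E)
  bf <- matrix(NA_real_, L, V, dimnames = list(colnames(f), colnames(E)))
  rho <- matrix(NA_real_, L, V, dimnames = dimnames(bf))
  yy <- colSums(Yw^2)
  set.seed(seed)
  run_seeds <- sample.int(1e6, n_runs)
  for (v in seq_len(V)) {
    xw <- Ew[, v]
    xx <- sum(xw^2)
    cv <- as.vector(crossprod(xw, Yw))
    ll0 <- -P / 2 * log(pmax(yy, 1e-12) / P)
    logmarg <- vapply(beta_grid, function(b) {
      rss <- pmax(yy - 2 * b * cv + b^2 * xx, 1e-12)
      -P / 2 * log(rss / P)
    }, numeric(L))
    if (L == 1) logmarg <- matrix(logmarg, nrow = 1)
    mx <- apply(logmarg, 1, max)
    bf[, v] <- rowSums(exp(logmarg - mx) *
                         rep(prior, each = L)) * exp(mx - ll0)
    rr <- matrix(0, L, n_runs)
    for (run in seq_len(n_runs)) {
      set.seed(run_seeds[run] + v)
      yj <- Yw + matrix(stats::rnorm(P * L, sd = 1e-7), P, L)
      xj <- xw + stats::rnorm(P, sd = 1e-7)
      rr[, run] <- suppressWarnings(
        stats::cor(apply(yj, 2, rank), rank(xj)))
    }
    rho[, v] <- rowMeans(rr)
  }
  structure(list(bf = bf, rho = rho, omega = omega), class = "env_assoc")
}

#' @export
print.env_assoc <- function(x, ...) {
  cat(sprintf("env_assoc: %d loci x %d variables; median BF %.3g\n",
              nrow(x$bf), ncol(x$bf), stats::median(x$bf)))
  invisible(x)
}

#' Robust outlier intersection
#'
#' The environmental-association set comprises loci that, for at least one
#' variable, sit in the top fraction of Bayes factors (inclusive of ties),
#' exceed the absolute BF cutoff and sit in the top fraction of absolute
#' Spearman correlations. The robust set is its intersection with the
#' q-significant PCA-scan set.
#'
#' @param pca a \code{pca_scan} result.
#' @param env an \code{env_assoc} result over the same loci.
#' @param bf_top top quantile of BF per variable (default top 1 percent).
#' @param bf_min absolute BF cutoff.
#' @param rho_top top quantile of |rho| per variable (default top 5
#'   percent).
#' @return an \code{outlier_set}: per-method locus id sets, the robust
#'   intersection, thresholds, and per-variable attribution of the env
#'   set.
#' @export
robust_outliers <- function(pca, env, bf_top = 0.01, bf_min = 3,
                            rho_top = 0.05) {
  loci <- pca$locus_id
  if (nrow(env$bf) != length(loci))
    stop("scans cover different locus universes")
  V <- ncol(env$bf)
  env_hit <- matrix(FALSE, length(loci), V)
  for (v in seq_len(V)) {
    bfv <- env$bf[, v]
    rhov <- abs(env$rho[, v])
    bf_thr <- stats::quantile(bfv, 1 - bf_top, na.rm = TRUE, names = FALSE)
    rho_thr <- stats::quantile(rhov, 1 - rho_top, na.rm = TRUE,
                               names = FALSE)
    env_hit[, v] <- !is.na(bfv) & bfv >= bf_thr & bfv > bf_min &
      !is.na(rhov) & rhov >= rho_thr
  }
  env_set <- loci[rowSums(env_hit) > 0]
  pca_set <- pca$significant
  robust <- intersect(env_set, pca_set)
  attribution <- data.frame(
    locus_id = rep(loci, V)[as.vector(env_hit)],
    variable = rep(colnames(env$bf) %||% paste0("var", seq_len(V)),
                   each = length(loci))[as.vector(env_hit)],
    bf = env$bf[env_hit], rho = env$rho[env_hit],
    stringsAsFactors = FALSE)
  structure(list(pca_set = pca_set, env_set = env_set, robust = robust,
                 thresholds = list(bf_top = bf_top, bf_min = bf_min,
                                   rho_top = rho_top, q_fdr = pca$fdr),
                 attribution = attribution),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set: %d PCA-scan, %d env-association, %d robust (intersection)\n",
              length(x$pca_set), length(x$env_set), length(x$robust)))
  invisible(x)
}

#' Window-based LD pruning
#'
#' Greedy r-squared pruning of loci in sliding windows (mean-imputed
#' dosages), mirroring the common 50-SNP window, 5-SNP step scheme.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param window window size in SNPs.
#' @param step step size in SNPs.
#' @param r2_max maximum squared correlation tolerated within a window.
#' @return logical vector of retained loci.
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_max = 0.05) {
  X <- G$calls
  for (j in seq_len(ncol(X))) {
    m <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- m
  }
  L <- ncol(X)
  keep <- rep(TRUE, L)
  starts <- seq(1, max(1, L - 1), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1, L)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    sds <- apply(X[, idx, drop = FALSE], 2, stats::sd)
    idx <- idx[sds > 0]
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(X[, idx, drop = FALSE])^2)
    for (a in seq_along(idx))
      for (b in seq_len(a - 1))
        if (keep[idx[a]] && keep[idx[b]] && is.finite(cc[a, b]) &&
            cc[a, b] > r2_max)
          keep[idx[a]] <- FALSE
  }
  keep
}

#' Putatively neutral, independent locus set
#'
#' Removes PCA-scan significant loci, then LD-prunes the remainder:
#' the construction of the covariance-null training set.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param pca a \code{pca_scan} result on \code{G}.
#' @param ... passed to \code{\link{ld_prune}}.
#' @return a \code{genotype_matrix} of neutral loci.
#' @export
neutral_set <- function(G, pca, ...) {
  nonsig <- !(G$locus_ids %in% pca$significant)
  G2 <- G[, nonsig]
  G2[, ld_prune(G2, ...)]
}
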