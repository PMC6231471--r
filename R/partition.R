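#' Trend-surface geographic predictors
#'
#' Second-order polynomial expansion of centered sampling coordinates:
#' columns x, y, xy, x^2, y^2. Degenerate geometries (constant or
#' collinear columns) are dropped with a warning.
#'
#' @param coords populations x 2 matrix or data frame of decimal-degree
#'   coordinates (x = longitude, y = latitude).
#' @return numeric matrix of spatial predictors (a constraint matrix with
#'   role "geog").
#' @export
trend_surface <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least three populations")
  x <- coords[, 1] - mean(coords[, 1])
  y <- coords[, 2] - mean(coords[, 2])
  M <- cbind(x = x, y = y, xy = x * y, x2 = x^2, y2 = y^2)
  keep <- apply(M, 2, function(col) stats::sd(col) > 1e-12)
  if (!all(keep)) {
    warning("dropping degenerate trend-surface columns: ",
            paste(colnames(M)[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
  }
  # drop exactly collinear columns
  q <- qr(M)
  if (q$rank < ncol(M)) {
    drop_cols <- setdiff(seq_len(ncol(M)), q$pivot[seq_len(q$rank)])
    warning("dropping collinear trend-surface columns: ",
            paste(colnames(M)[drop_cols], collapse = ", "))
    M <- M[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  rownames(M) <- rownames(coords)
  M
}

#' Reduce a predictor table by correlation-matrix PCA
#'
#' Principal components of the correlation matrix, retained by one of
#' three criteria: cumulative variance explained, eigenvalue greater than
#' one (Kaiser), or a fixed axis count. Constant columns are dropped with
#' a warning. If the eigenvalue criterion retains nothing (isotropic
#' input), PC1 is kept as a fallback.
#'
#' @param M populations x variables matrix.
#' @param criterion \code{"cum_var"}, \code{"eigenvalue"} or
#'   \code{"fixed"}.
#' @param cum_var cumulative variance target for \code{"cum_var"}.
#' @param k axis count for \code{"fixed"}.
#' @return list with \code{scores} (retained PC scores), \code{loadings},
#'   \code{eigenvalues} and \code{cum_var_explained}.
#' @export
pca_reduce <- function(M, criterion = c("cum_var", "eigenvalue", "fixed"),
                       cum_var = 0.75, k = 2) {
  criterion <- match.arg(criterion)
  M <- as.matrix(M)
  if (ncol(M) < 2) stop("need at least two columns to reduce")
  keep <- apply(M, 2, function(col) stats::sd(col) > 1e-12)
  if (!all(keep)) {
    warning("dropping constant columns: ",
            paste(colnames(M)[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  cum <- cumsum(eig) / sum(eig)
  n_axes <- switch(criterion,
                   cum_var = which(cum >= cum_var)[1],
                   eigenvalue = sum(eig > 1),
                   fixed = min(k, length(eig)))
  if (is.na(n_axes) || n_axes < 1) n_axes <- 1L
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  rownames(scores) <- rownames(M)
  list(scores = scores, loadings = pc$rotation[, seq_len(n_axes),
                                               drop = FALSE],
       eigenvalues = eig, cum_var_explained = cum[n_axes])
}

freqs_response <- function(F) {
  f <- if (inherits(F, "pop_freqs")) F$freq else as.matrix(F)
  # flagged cells (no data) are imputed at the across-population mean so
  # they contribute nothing to among-population variance
  if (anyNA(f)) {
    mu <- colMeans(f, na.rm = TRUE)
    idx <- which(is.na(f), arr.ind = TRUE)
    f[idx] <- mu[idx[, 2]]
  }
  f
}

#' Redundancy analysis of population allele frequencies
#'
#' Constrained ordination of the (centered) population x locus frequency
#' matrix on a predictor matrix, optionally conditioned on covariates
#' (partial RDA). Backed by \code{vegan::rda}.
#'
#' @param F \code{pop_freqs} or populations x loci frequency matrix.
#' @param X constraint matrix (populations x predictors).
#' @param Z optional conditioning matrix.
#' @return an \code{rda_result}: \code{r2} (constrained proportion),
#'   \code{adj_r2} (Ezekiel), canonical axes, and the underlying vegan
#'   fit.
#' @export
rda_freqs <- function(F, X, Z = NULL) {
  f <- freqs_response(F)
  X <- as.matrix(X)
  if (nrow(X) != nrow(f)) stop("predictor rows must match populations")
  p_tot <- ncol(X) + if (is.null(Z)) 0 else ncol(as.matrix(Z))
  if (p_tot >= nrow(f))
    stop(sprintf("predictors (%d) must be fewer than populations (%d)",
                 p_tot, nrow(f)))
  fit <- if (is.null(Z)) vegan::rda(f ~ X)
         else vegan::rda(f ~ X + Condition(Z))
  r2 <- fit$CCA$tot.chi / fit$tot.chi
  adj <- vegan::RsquareAdj(fit)
  axes <- suppressWarnings(
    tryCatch(vegan::scores(fit, display = "lc",
                           choices = seq_len(min(3, fit$CCA$rank))),
             error = function(e) NULL))
  structure(list(r2 = r2, adj_r2 = adj$adj.r.squared %||% NA_real_,
                 axes = axes, fit = fit,
                 n = nrow(f), p = ncol(X)),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("rda_result: R2 = %.4f, adjusted R2 = %.4f (n = %d, p = %d)\n",
              x$r2, x$adj_r2, x$n, x$p))
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' 1 - (1 - R2)(n - 1)/(n - p - 1); undefined (error) when n <= p + 1.
#' With zero predictors the input is returned unchanged.
#'
#' @param r2 unadjusted proportion of variance.
#' @param n number of observations (populations).
#' @param p number of predictors.
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (p == 0) return(r2)
  if (n <= p + 1) stop("adjusted R2 undefined: n <= p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Permutation test of an (partial) RDA
#'
#' Pseudo-F permutation test: p = (1 + number of permuted pseudo-F >=
#' observed) / (1 + n_perm), permuting population rows (residualized rows
#' under a conditioning matrix). Backed by \code{vegan::anova.cca}.
#'
#' @param F response (\code{pop_freqs} or matrix).
#' @param X constraint matrix.
#' @param Z optional conditioning matrix.
#' @param n_perm number of permutations.
#' @param seed integer seed (fixed seed gives a reproducible p).
#' @return list with \code{p}, \code{F_stat} and \code{n_perm}.
#' @export
permutation_test <- function(F, X, Z = NULL, n_perm = 999, seed = 1) {
  f <- freqs_response(F)
  X <- as.matrix(X)
  set.seed(seed)
  fit <- if (is.null(Z)) vegan::rda(f ~ X)
         else vegan::rda(f ~ X + Condition(Z))
  # degenerate extreme: constraints absorb (essentially) all variance, so
  # no permutation can reach the observed pseudo-F
  if (is.null(fit$CA) || fit$CA$tot.chi < 1e-10 * fit$tot.chi)
    return(list(p = 1 / (1 + n_perm), F_stat = Inf, n_perm = n_perm))
  an <- vegan::anova.cca(fit, permutations = permute::how(nperm = n_perm))
  list(p = an$`Pr(>F)`[1], F_stat = an$F[1], n_perm = n_perm)
}

#' Forward selection of constraint columns
#'
#' A global permutation test of the full candidate matrix gates the
#' procedure (the standard double stopping rule that keeps the family-wise
#' entry rate at alpha); if it passes, candidates are added one at a time,
#' each requiring permutation p < alpha and an improved adjusted
#' R-squared. May select nothing.
#'
#' @param F response (\code{pop_freqs} or matrix).
#' @param candidates matrix of candidate predictor columns.
#' @param alpha significance threshold for entry.
#' @param n_perm permutations per candidate test.
#' @param seed integer seed.
#' @return character vector of selected column names (possibly empty).
#' @export
forward_select <- function(F, candidates, alpha = 0.05, n_perm = 999,
                           seed = 1) {
  f <- freqs_response(F)
  candidates <- as.matrix(candidates)
  if (ncol(candidates) == 0) stop("no candidate columns")
  nm <- colnames(candidates) %||% paste0("c", seq_len(ncol(candidates)))
  colnames(candidates) <- nm
  if (ncol(candidates) < nrow(f) - 1 &&
      permutation_test(f, candidates, n_perm = n_perm,
                       seed = seed + 991)$p >= alpha)
    return(character(0))
  selected <- character(0)
  cur_adj <- 0
  repeat {
    remaining <- setdiff(nm, selected)
    if (length(remaining) == 0) break
    if (length(selected) + 1 >= nrow(f) - 1) break
    best <- NULL
    for (cand in remaining) {
      X <- candidates[, cand, drop = FALSE]
      Z <- if (length(selected))
        candidates[, selected, drop = FALSE] else NULL
      pt <- permutation_test(f, X, Z, n_perm = n_perm,
                             seed = seed + length(selected))
      full <- rda_freqs(f, candidates[, c(selected, cand), drop = FALSE])
      if (is.null(best) || pt$p < best$p ||
          (pt$p == best$p && full$adj_r2 > best$adj))
        best <- list(cand = cand, p = pt$p, adj = full$adj_r2)
    }
    if (best$p < alpha && best$adj > cur_adj) {
      selected <- c(selected, best$cand)
      cur_adj <- best$adj
    } else break
  }
  selected
}

#' Partition among-population genomic variance into environment,
#' geography and colonization fractions
#'
#' The adjusted-R-squared ledger: marginal ("combined") fractions for each
#' predictor set, conditional ("individual") fractions for environment
#' given geography and vice versa obtained by subtraction of nested
#' adjusted R-squared values, their confounded joint fraction, total
#' explained (environment and geography jointly) and total unexplained.
#' The colonization (mitotype) matrix is reported marginally with its
#' significance only; the joint environment-geography fraction carries no
#' test.
#'
#' @param F response: \code{pop_freqs} or populations x loci matrix.
#' @param env environment constraint matrix (e.g. retained PCs).
#' @param geog geography constraint matrix (e.g. selected trend-surface
#'   columns).
#' @param mito optional colonization constraint matrix (mitotype
#'   frequency PCs).
#' @param n_perm permutations for the significance tests.
#' @param seed integer seed.
#' @return a \code{partition_table}.
#' @export
variance_partition <- function(F, env, geog, mito = NULL, n_perm = 999,
                               seed = 1) {
  f <- freqs_response(F)
  env <- as.matrix(env)
  geog <- as.matrix(geog)
  r_env <- rda_freqs(f, env)
  r_geog <- rda_freqs(f, geog)
  r_both <- rda_freqs(f, cbind(env, geog))
  led <- fraction_ledger(r_env$adj_r2, r_geog$adj_r2, r_both$adj_r2)
  p_env <- permutation_test(f, env, n_perm = n_perm, seed = seed)$p
  p_geog <- permutation_test(f, geog, n_perm = n_perm, seed = seed + 1)$p
  p_env_geog <- permutation_test(f, env, geog, n_perm = n_perm,
                                 seed = seed + 2)$p
  p_geog_env <- permutation_test(f, geog, env, n_perm = n_perm,
                                 seed = seed + 3)$p
  mito_adj <- NA_real_
  p_mito <- NA_real_
  if (!is.null(mito)) {
    mito <- as.matrix(mito)
    mito_adj <- rda_freqs(f, mito)$adj_r2
    p_mito <- permutation_test(f, mito, n_perm = n_perm, seed = seed + 4)$p
  }
  tab <- data.frame(
    fraction = c("F~env.", "F~geog.", "F~mito.", "F~env.|geog.",
                 "F~geog.|env.", "F~env.+geog.", "Total explained",
                 "Total unexplained"),
    adj_r2 = c(r_env$adj_r2, r_geog$adj_r2, mito_adj, led$env_given_geog,
               led$geog_given_env, led$joint, led$total_explained,
               led$total_unexplained),
    p = c(p_env, p_geog, p_mito, p_env_geog, p_geog_env, NA, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, ledger = led, n_perm = n_perm, seed = seed),
            class = "partition_table")
}

#' Adjusted-R-squared fraction arithmetic
#'
#' The subtraction ledger behind the partition table: given marginal
#' adjusted R-squared values for environment, geography and their union,
#' the conditional fractions are differences of nested models, the joint
#' (confounded) fraction is adj(env) + adj(geog) - adj(both), total
#' explained is adj(both). The identity env|geog + geog|env + joint =
#' total holds exactly at full precision.
#'
#' @param adj_env,adj_geog,adj_both marginal adjusted R-squared values.
#' @return list of fractions.
#' @export
fraction_ledger <- function(adj_env, adj_geog, adj_both) {
  list(env = adj_env, geog = adj_geog,
       env_given_geog = adj_both - adj_geog,
       geog_given_env = adj_both - adj_env,
       joint = adj_env + adj_geog - adj_both,
       total_explained = adj_both,
       total_unexplained = 1 - adj_both)
}

#' @export
print.partition_table <- function(x, digits = 3, ...) {
  tab <- x$table
  stars <- ifelse(is.na(tab$p), "",
                  ifelse(tab$p < 0.01, "**",
                         ifelse(tab$p < 0.05, "*", " ns")))
  cat("Partition of among-population genomic variance (adjusted R2)\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-18s %8s%s\n", tab$fraction[i],
                ifelse(is.na(tab$adj_r2[i]), "-",
                       formatC(tab$adj_r2[i], digits = digits,
                               format = "f")), stars[i]))
  cat(sprintf("  (%d permutations; joint fraction untested)\n", x$n_perm))
  invisible(x)
}

#' Mitotype frequency predictor matrix
#'
#' Per-population mitotype frequencies (singleton mitotypes removed),
#' reduced by correlation PCA to the axes reaching the cumulative-variance
#' target: the colonization-history constraint matrix.
#'
#' @param mitotypes named vector individual -> mitotype label.
#' @param popmap named vector individual -> population.
#' @param cum_var cumulative variance target for retained PCs.
#' @return list with \code{scores} (populations x PCs) and the frequency
#'   matrix.
#' @export
mito_constraints <- function(mitotypes, popmap, cum_var = 0.75) {
  ind <- names(mitotypes)
  if (is.null(ind)) stop("mitotypes must be a named vector")
  pop <- factor(popmap[ind])
  tab <- table(pop, mitotypes)
  singleton <- colSums(tab) == 1
  if (any(singleton)) tab <- tab[, !singleton, drop = FALSE]
  freq <- sweep(unclass(tab), 1, rowSums(tab), "/")
  red <- pca_reduce(freq, criterion = "cum_var", cum_var = cum_var)
  list(scores = red$scores, freq = freq,
       cum_var_explained = red$cum_var_explained)
}
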