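#' Isolation-with-migration model parameters
#'
#' Parameters of the three-population divergence model: an outgroup splits
#' from the ancestor of the two remaining groups at \code{T1} generations
#' ago, the two sisters split at \code{T2} (\code{T2 < T1}), with
#' continuous migration among the three extant groups since their splits.
#' Which group is the outgroup is set by \code{branching_order}.
#'
#' @param Ne length-3 vector of current diploid effective sizes, in the
#'   fixed group order (south, north, west).
#' @param Ne_anc1 diploid size of the sister-pair ancestor.
#' @param Ne_anc2 diploid size of the root population.
#' @param T1 root split time in generations (> T2).
#' @param T2 sister split time in generations.
#' @param mig backward per-lineage migration rate per generation: a single
#'   symmetric rate or a 3x3 matrix \code{mig[i, j]} (rate at which a
#'   lineage currently in group i traces back to group j). The forward
#'   number of migrants into group i per generation is approximately
#'   \code{mig[i, j] * Ne[i]}. Ignored when \code{mig_migrants} is given.
#' @param mig_migrants alternative migration parameterization: migrants
#'   per generation (single symmetric value or 3x3 matrix
#'   \code{M[i, j]}, forward migrants into group i from group j); the
#'   backward rate is derived as \code{M[i, j] / Ne[i]} at simulation
#'   time, which keeps the coalescent event count bounded when sizes are
#'   varied during fitting.
#' @param growth_mode one of \code{"constant"}, \code{"exponential"}
#'   (descendant groups grew exponentially since their split) or
#'   \code{"recent_exponential"} (growth confined to the most recent
#'   fraction \code{recent_frac} of each branch).
#' @param growth_factor fold-change from founding to current size under
#'   the growth modes.
#' @param recent_frac fraction of a branch over which recent growth acts.
#' @param branching_order which group diverged first:
#'   \code{"south_first"}, \code{"north_first"} or \code{"west_first"}.
#' @return an \code{im_params} object.
#' @export
im_params <- function(Ne = c(south = 1e5, north = 2e5, west = 1e5),
                      Ne_anc1 = 1e5, Ne_anc2 = 1e5,
                      T1 = 7e4, T2 = 1e4, mig = 0, mig_migrants = NULL,
                      growth_mode = c("constant", "exponential",
                                      "recent_exponential"),
                      growth_factor = 10, recent_frac = 0.1,
                      branching_order = c("south_first", "north_first",
                                          "west_first")) {
  growth_mode <- match.arg(growth_mode)
  branching_order <- match.arg(branching_order)
  Ne <- unname(as.numeric(Ne))
  stopifnot(length(Ne) == 3)
  if (any(c(Ne, Ne_anc1, Ne_anc2) <= 0)) stop("effective sizes must be > 0")
  if (!(T1 > 0 && T2 > 0)) stop("split times must be > 0")
  if (T1 < T2) stop("impossible topology: T2 must not exceed T1")
  if (is.finite(T1) && is.finite(T2) && T1 == T2)
    stop("impossible topology: T2 must be strictly below T1")
  expand3 <- function(m) {
    if (length(m) == 1) {
      m <- matrix(m, 3, 3)
      diag(m) <- 0
    }
    m <- as.matrix(m)
    stopifnot(all(dim(m) == c(3, 3)))
    if (any(m < 0)) stop("migration rates must be >= 0")
    m
  }
  mig <- expand3(mig)
  if (!is.null(mig_migrants)) mig_migrants <- expand3(mig_migrants)
  structure(list(Ne = Ne, Ne_anc1 = Ne_anc1, Ne_anc2 = Ne_anc2,
                 T1 = T1, T2 = T2, mig = mig,
                 mig_migrants = mig_migrants, growth_mode = growth_mode,
                 growth_factor = growth_factor, recent_frac = recent_frac,
                 branching_order = branching_order),
            class = "im_params")
}

#' @export
print.im_params <- function(x, ...) {
  cat("im_params:", x$branching_order, "/", x$growth_mode, "\n")
  cat(sprintf("  Ne (south, north, west): %s; anc1 %.3g; root %.3g\n",
              paste(signif(x$Ne, 3), collapse = ", "),
              x$Ne_anc1, x$Ne_anc2))
  if (!is.null(x$mig_migrants))
    cat(sprintf("  T1 %.4g, T2 %.4g generations; max %.3g migrants/gen\n",
                x$T1, x$T2, max(x$mig_migrants)))
  else
    cat(sprintf("  T1 %.4g, T2 %.4g generations; max mig rate %.3g\n",
                x$T1, x$T2, max(x$mig)))
  invisible(x)
}

#' Demographic model specification
#'
#' One of the nine isolation-with-migration models: three branching orders
#' crossed with three growth modes, plus the list of parameters left free
#' during fitting.
#'
#' @param branching_order which group split first.
#' @param growth_mode population size trajectory of descendant groups.
#' @param free character vector of free-parameter names for
#'   \code{\link{fit_im}}.
#' @return a \code{model_spec} object.
#' @export
model_spec <- function(branching_order = c("south_first", "north_first",
                                           "west_first"),
                       growth_mode = c("constant", "exponential",
                                       "recent_exponential"),
                       free = c("Ne_south", "Ne_north", "Ne_west",
                                "Ne_anc1", "Ne_anc2", "T1", "T2", "mig")) {
  structure(list(branching_order = match.arg(branching_order),
                 growth_mode = match.arg(growth_mode), free = free),
            class = "model_spec")
}

#' All nine candidate IM models
#'
#' @param free free-parameter list applied to every model.
#' @return named list of \code{\link{model_spec}} objects.
#' @export
all_im_models <- function(free = c("Ne_south", "Ne_north", "Ne_west",
                                   "Ne_anc1", "Ne_anc2", "T1", "T2",
                                   "mig")) {
  orders <- c("south_first", "north_first", "west_first")
  growths <- c("constant", "exponential", "recent_exponential")
  out <- list()
  for (o in orders)
    for (g in growths)
      out[[paste(o, g, sep = ".")]] <- model_spec(o, g, free)
  out
}

group_order <- c("south", "north", "west")

# deme-ordered haploid sizes (zeros for unsampled demes) of an observed SFS
sfs_deme_sizes <- function(obs) {
  if (!is.null(obs$groups)) {
    nh <- integer(3)
    nh[match(obs$groups, group_order)] <- obs$dims
    return(nh)
  }
  c(obs$dims, rep(0L, max(0, 3 - length(obs$dims))))[1:3]
}

# translate im_params (+ optional model overrides) into engine arguments
engine_args <- function(params, model = NULL) {
  bo <- if (!is.null(model)) model$branching_order else params$branching_order
  gm <- if (!is.null(model)) model$growth_mode else params$growth_mode
  f <- match(sub("_first$", "", bo), group_order) - 1L
  dur <- ifelse(seq_len(3) - 1L == f, params$T1, params$T2)
  r <- rep(0, 3)
  t_end <- rep(0, 3)
  if (gm != "constant") {
    span <- if (gm == "exponential") dur else params$recent_frac * dur
    span[!is.finite(span)] <- 0      # no growth on unbounded branches
    r <- ifelse(span > 0, log(params$growth_factor) / span, 0)
    t_end <- span
  }
  mig <- if (!is.null(params$mig_migrants))
    params$mig_migrants / params$Ne else params$mig
  list(f = f, T1 = params$T1, T2 = params$T2, Ne = params$Ne,
       Ne_anc1 = params$Ne_anc1, Ne_anc2 = params$Ne_anc2,
       r = r, t_end = t_end, mig = mig)
}

#' Simulate unlinked biallelic SNPs under an IM model
#'
#' Coalescent simulation of independent single-site genealogies under the
#' three-population isolation-with-migration model, with one infinite-sites
#' mutation per locus dropped uniformly on the genealogy (conditioning each
#' site to be segregating). Haploid genomes are paired into diploid
#' individuals.
#'
#' @param params an \code{\link{im_params}} object.
#' @param n_loci number of unlinked SNPs.
#' @param samples_per_pop diploid sample sizes, length 3 in the group
#'   order (south, north, west); zeros allowed.
#' @param seed integer seed (the simulation is deterministic per seed).
#' @param loci_per_fragment loci are tagged into fragments of this size,
#'   used as blocks by \code{\link{block_bootstrap_ci}}.
#' @return list with \code{G} (a \code{\link{genotype_matrix}}) and
#'   \code{popmap} (individual -> group).
#' @export
simulate_im <- function(params, n_loci, samples_per_pop, seed = 1,
                        loci_per_fragment = 1) {
  stopifnot(inherits(params, "im_params"), n_loci >= 1)
  samples_per_pop <- as.integer(samples_per_pop)
  stopifnot(length(samples_per_pop) == 3, all(samples_per_pop >= 0),
            sum(samples_per_pop) >= 1)
  ea <- engine_args(params)
  # exact length-weighted site sampling in two passes over a common
  # genealogy stream: sites fall on genealogies proportional to their
  # total branch length (the infinite-sites segregating-site measure)
  set.seed(seed)
  len <- cpp_sim_lengths(2L * samples_per_pop, ea$f, ea$T1, ea$T2, ea$Ne,
                         ea$Ne_anc1, ea$Ne_anc2, ea$r, ea$t_end, ea$mig,
                         as.integer(n_loci))
  m <- as.vector(stats::rmultinom(1, n_loci, len / sum(len)))
  set.seed(seed)
  hap <- cpp_sim_sites(2L * samples_per_pop, ea$f, ea$T1, ea$T2, ea$Ne,
                       ea$Ne_anc1, ea$Ne_anc2, ea$r, ea$t_end, ea$mig,
                       m, as.integer(seed %% 100000 + 7))
  odd <- seq(1, nrow(hap), by = 2)
  calls <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  grp <- rep(group_order, samples_per_pop)
  ids <- paste0(grp, ".", unlist(lapply(samples_per_pop, seq_len)))
  frag <- paste0("frag", (seq_len(n_loci) - 1) %/% loci_per_fragment + 1)
  G <- genotype_matrix(calls, individual_ids = ids,
                       locus_ids = paste0("snp", seq_len(n_loci)),
                       fragments = frag)
  popmap <- stats::setNames(grp, ids)
  list(G = G, popmap = popmap)
}

#' Folded joint site-frequency spectrum container
#'
#' @param entries array of per-cell masses over joint minor-allele-count
#'   cells; dimensions are \code{haploid_sizes + 1}. Non-representative
#'   (folded-away) cells are zero.
#' @param haploid_sizes per-group haploid sample sizes.
#' @param normalized whether entries sum to one (expected spectra) rather
#'   than to a SNP count (observed spectra).
#' @param monomorphic_excluded,singletons_excluded masses removed from the
#'   spectrum, reported for accounting.
#' @param n_sims Monte-Carlo simulation count behind an expected spectrum
#'   (drives the zero-cell floor in \code{\link{composite_loglik}}).
#' @param groups optional group labels per dimension (e.g. "south",
#'   "north", "west"); lets fitting map dimensions onto model demes.
#' @return a \code{folded_sfs} object.
#' @export
folded_sfs <- function(entries, haploid_sizes, normalized = FALSE,
                       monomorphic_excluded = 0, singletons_excluded = 0,
                       n_sims = NULL, groups = NULL) {
  entries <- as.array(entries)
  stopifnot(all(dim(entries) == haploid_sizes + 1))
  if (any(entries < 0)) stop("SFS entries must be non-negative")
  structure(list(entries = entries, dims = as.integer(haploid_sizes),
                 groups = groups,
                 n_snps = sum(entries), normalized = normalized,
                 monomorphic_excluded = monomorphic_excluded,
                 singletons_excluded = singletons_excluded,
                 n_sims = n_sims),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded_sfs over haploid sizes (%s): total mass %.4g%s\n",
              paste(x$dims, collapse = ", "), x$n_snps,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

# fold an unfolded joint count array onto minor-allele configurations;
# each cell is merged with its complement, the representative being the
# cell with the smaller total derived count (ties: smaller linear index,
# self-complementary cells kept once, i.e. half weight per member)
fold_array <- function(arr) {
  dims <- dim(arr)
  if (is.null(dims)) dims <- length(arr)
  sizes <- dims - 1L
  M <- sum(sizes)
  idx <- arrayInd(seq_along(arr), dims) - 1L
  tot <- rowSums(idx)
  comp <- sweep(-idx, 2, sizes, "+")
  mult <- cumprod(c(1, dims[-length(dims)]))
  lin_comp <- as.vector(comp %*% mult) + 1
  lin <- seq_along(arr)
  rep_cell <- tot < M / 2 | (tot == M / 2 & lin <= lin_comp)
  out <- array(0, dims)
  v <- as.vector(arr)
  add <- ifelse(lin == lin_comp, 0, v[lin_comp])
  out[lin[rep_cell]] <- v[lin[rep_cell]] + add[rep_cell]
  out
}

# logical mask of representative, non-monomorphic cells of a folded array
sfs_cell_mask <- function(dims_entries) {
  dims <- dims_entries
  sizes <- dims - 1L
  M <- sum(sizes)
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  tot <- rowSums(idx)
  comp <- sweep(-idx, 2, sizes, "+")
  mult <- cumprod(c(1, dims[-length(dims)]))
  lin_comp <- as.vector(comp %*% mult) + 1
  lin <- seq_len(prod(dims))
  rep_cell <- tot < M / 2 | (tot == M / 2 & lin <= lin_comp)
  mono <- tot == 0 | tot == M
  array(rep_cell & !mono, dims)
}

# per-cell folded minor total (minimum of derived and ancestral totals)
sfs_minor_total <- function(dims) {
  sizes <- dims - 1L
  M <- sum(sizes)
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  array(pmin(rowSums(idx), M - rowSums(idx)), dims)
}

#' Project observed genotypes onto a folded joint SFS by hypergeometric
#' down-sampling
#'
#' Each site contributes its expected joint allele-count distribution when
#' the observed non-missing allele counts are down-sampled (without
#' replacement) to the target haploid sizes, maximizing the number of
#' sites retained in the presence of missing data. Sites where any group
#' has fewer non-missing alleles than its target are skipped and counted.
#' Mass that is monomorphic after projection is excluded and reported.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named vector mapping individual id to group.
#' @param target_haploid_sizes named (by group) or ordered vector of
#'   target haploid sample sizes.
#' @param exclude_singletons drop folded cells with joint minor count 1
#'   (low-confidence rare alleles).
#' @return a \code{\link{folded_sfs}}; attributes report skipped sites.
#' @export
project_folded_sfs <- function(G, popmap, target_haploid_sizes,
                               exclude_singletons = FALSE) {
  pop <- check_popmap(G, popmap)
  m <- as.integer(target_haploid_sizes)
  if (any(m <= 0)) stop("target haploid sizes must be positive")
  grps <- if (!is.null(names(target_haploid_sizes)))
    names(target_haploid_sizes) else levels(pop)
  if (!all(grps %in% levels(pop)))
    stop("target sizes name groups absent from the popmap")
  if (all(grps %in% group_order)) {
    # keep demes in canonical order so fitting can map them
    o <- order(match(grps, group_order))
    grps <- grps[o]
    m <- m[o]
  }
  K <- length(m)
  nonmiss <- !is.na(G$calls)
  calls0 <- G$calls
  calls0[!nonmiss] <- 0L
  d <- t(rowsum(calls0, pop)[grps, , drop = FALSE])        # loci x groups alt
  n <- t(2 * rowsum(nonmiss + 0L, pop)[grps, , drop = FALSE])
  usable <- rowSums(n >= rep(m, each = nrow(n))) == K
  dims <- m + 1L
  arr <- array(0, dims)
  if (any(usable)) {
    du <- d[usable, , drop = FALSE]
    nu <- n[usable, , drop = FALSE]
    key <- do.call(paste, c(as.data.frame(cbind(du, nu)), sep = "_"))
    tab <- table(key)
    first <- !duplicated(key)
    dk <- du[first, , drop = FALSE]
    nk <- nu[first, , drop = FALSE]
    w <- as.numeric(tab[key[first]])
    for (u in seq_len(nrow(dk))) {
      probs <- lapply(seq_len(K), function(g)
        stats::dhyper(0:m[g], dk[u, g], nk[u, g] - dk[u, g], m[g]))
      joint <- Reduce(function(a, b) outer(a, b), probs)
      arr <- arr + w[u] * joint
    }
  }
  mono <- arr[rbind(rep(1L, K))] + arr[rbind(dims)]
  arr[rbind(rep(1L, K))] <- 0
  arr[rbind(dims)] <- 0
  folded <- fold_array(arr)
  singleton_mass <- 0
  if (exclude_singletons) {
    minor1 <- sfs_minor_total(dims) == 1
    singleton_mass <- sum(folded[minor1])
    folded[minor1] <- 0
  }
  out <- folded_sfs(folded, m, normalized = FALSE,
                    monomorphic_excluded = mono,
                    singletons_excluded = singleton_mass,
                    groups = if (all(grps %in% group_order)) grps else NULL)
  attr(out, "n_sites_used") <- sum(usable)
  attr(out, "n_sites_skipped") <- sum(!usable)
  out
}

#' Expected folded joint SFS under an IM model
#'
#' Monte-Carlo estimate of the per-cell probability of a segregating site,
#' obtained by accumulating expected branch lengths by descendant
#' configuration over simulated genealogies (every branch contributes,
#' which is far more efficient than per-site mutation sampling).
#'
#' @param params an \code{\link{im_params}}.
#' @param samples_haploid per-group haploid sample sizes (length 3 in the
#'   group order south, north, west; zeros allowed).
#' @param model optional \code{\link{model_spec}} overriding the branching
#'   order and growth mode in \code{params}.
#' @param n_sims number of simulated genealogies (>= 1000 recommended).
#' @param seed integer seed; fixing it gives common random numbers across
#'   parameter values, which smooths likelihood surfaces.
#' @param exclude_singletons drop folded cells with joint minor count 1.
#' @return a normalized \code{\link{folded_sfs}}.
#' @export
expected_sfs <- function(params, samples_haploid, model = NULL,
                         n_sims = 1000, seed = 1,
                         exclude_singletons = FALSE) {
  stopifnot(inherits(params, "im_params"), n_sims >= 10)
  nh <- as.integer(samples_haploid)
  stopifnot(length(nh) == 3, all(nh >= 0), sum(nh) >= 2)
  ea <- engine_args(params, model)
  set.seed(seed)
  arr <- cpp_branch_sfs(nh, ea$f, ea$T1, ea$T2, ea$Ne, ea$Ne_anc1,
                        ea$Ne_anc2, ea$r, ea$t_end, ea$mig,
                        as.integer(n_sims))
  # keep only sampled groups' axes
  keep <- nh > 0
  if (!all(keep)) {
    arr <- apply(arr, which(keep), sum)
    arr <- array(arr, nh[keep] + 1L)
    nh <- nh[keep]
  }
  dims <- dim(arr)
  arr[rbind(rep(1L, length(dims)))] <- 0
  arr[rbind(dims)] <- 0
  folded <- fold_array(arr)
  if (exclude_singletons)
    folded[sfs_minor_total(dims) == 1] <- 0
  tot <- sum(folded)
  if (tot <= 0) stop("no segregating branch mass simulated")
  folded_sfs(folded / tot, nh, normalized = TRUE, n_sims = n_sims)
}

#' Multinomial composite log-likelihood of an observed folded SFS
#'
#' Treats SFS cells as independent multinomial draws conditional on
#' segregating: logL = sum over cells of obs * log(expected proportion).
#' Expected cells at zero are floored at 1/(10 * n_sims) so a configuration
#' never seen in the Monte-Carlo sample contributes a large but finite
#' penalty.
#'
#' @param obs observed \code{\link{folded_sfs}} (counts).
#' @param expected normalized expected \code{\link{folded_sfs}}.
#' @return composite log-likelihood (numeric).
#' @export
composite_loglik <- function(obs, expected) {
  stopifnot(inherits(obs, "folded_sfs"), inherits(expected, "folded_sfs"))
  if (!identical(obs$dims, expected$dims))
    stop("observed and expected SFS dimensions differ")
  if (!expected$normalized) stop("expected SFS must be normalized")
  floor_p <- 1 / (10 * (expected$n_sims %||% 1e6))
  mask <- sfs_cell_mask(obs$dims + 1L)
  o <- obs$entries[mask]
  e <- pmax(expected$entries[mask], floor_p)
  sum(o * log(e))
}

#' Akaike weights over a set of fitted models
#'
#' AIC = 2k - 2 logL; weights w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2).
#'
#' @param fits a list of \code{im_fit} objects, or a data frame with
#'   columns \code{logL} and \code{k}.
#' @return data frame: model, logL, k, AIC, dAIC, weight.
#' @export
akaike_weights <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits
    if (is.null(tab$model)) tab$model <- paste0("model", seq_len(nrow(tab)))
  } else {
    tab <- data.frame(
      model = names(fits) %||% paste0("model", seq_along(fits)),
      logL = vapply(fits, function(f) f$loglik, numeric(1)),
      k = vapply(fits, function(f) f$k, numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (nrow(tab) < 2) stop("need at least two models to compare")
  tab$AIC <- 2 * tab$k - 2 * tab$logL
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$weight <- exp(-tab$dAIC / 2) / sum(exp(-tab$dAIC / 2))
  tab[order(tab$dAIC), ]
}

default_im_bounds <- function() {
  list(Ne_south = c(1e3, 1e7), Ne_north = c(1e3, 1e7),
       Ne_west = c(1e3, 1e7), Ne_anc1 = c(1e3, 1e7),
       Ne_anc2 = c(1e3, 1e7), T1 = c(1e2, 1e7), T2 = c(1e2, 1e7),
       mig = c(0.05, 50))
}

get_im_par <- function(params, name) {
  switch(name,
         Ne_south = params$Ne[1], Ne_north = params$Ne[2],
         Ne_west = params$Ne[3], Ne_anc1 = params$Ne_anc1,
         Ne_anc2 = params$Ne_anc2, T1 = params$T1, T2 = params$T2,
         mig = if (!is.null(params$mig_migrants))
           max(params$mig_migrants) else max(params$mig))
}

set_im_par <- function(params, name, value) {
  if (name == "Ne_south") params$Ne[1] <- value
  else if (name == "Ne_north") params$Ne[2] <- value
  else if (name == "Ne_west") params$Ne[3] <- value
  else if (name == "Ne_anc1") params$Ne_anc1 <- value
  else if (name == "Ne_anc2") params$Ne_anc2 <- value
  else if (name == "T1") params$T1 <- value
  else if (name == "T2") params$T2 <- value
  else if (name == "mig") {
    # free migration is fitted on the migrants-per-generation scale
    params$mig_migrants <- matrix(value, 3, 3)
    diag(params$mig_migrants) <- 0
  } else stop("unknown parameter: ", name)
  params
}

#' Fit an IM model to an observed folded SFS by composite likelihood
#'
#' Multi-start conditional maximization: each run draws a log-uniform
#' starting point inside the parameter bounds and cycles coordinate-wise
#' one-dimensional (Brent) maximizations of the composite likelihood on
#' log-scaled parameters. The expected SFS is Monte-Carlo estimated with
#' common random numbers per run, making each run's objective deterministic
#' and its likelihood trace monotone non-decreasing.
#'
#' @param obs observed \code{\link{folded_sfs}} over three groups.
#' @param model a \code{\link{model_spec}} (branching order, growth mode,
#'   free parameters).
#' @param init optional \code{\link{im_params}} starting point (also the
#'   source of fixed-parameter values); defaults to bound midpoints on the
#'   log scale.
#' @param bounds named list of c(lower, upper) per parameter.
#' @param n_runs independent restarts.
#' @param cycles conditional maximization cycles per run.
#' @param n_sims Monte-Carlo genealogies per expected-SFS evaluation.
#' @param polish_sims when positive, the best run is refined by one
#'   further conditional-maximization cycle at this (larger) simulation
#'   count, damping Monte-Carlo noise around the optimum.
#' @param seed integer seed; run r uses stream seed + r.
#' @return an \code{im_fit}: best parameters, composite log-likelihood,
#'   AIC ingredients, per-run traces and a convergence flag.
#' @export
fit_im <- function(obs, model, init = NULL, bounds = default_im_bounds(),
                   n_runs = 5, cycles = 3, n_sims = 500, polish_sims = 0,
                   seed = 1) {
  stopifnot(inherits(obs, "folded_sfs"), inherits(model, "model_spec"))
  if (sum(obs$entries) <= 0) stop("observed SFS is empty")
  nh <- sfs_deme_sizes(obs)
  free <- model$free
  excl1 <- obs$singletons_excluded > 0
  if (is.null(init)) {
    init <- im_params(branching_order = model$branching_order,
                      growth_mode = model$growth_mode)
    for (nm in free)
      init <- set_im_par(init, nm, exp(mean(log(bounds[[nm]]))))
  }
  init$branching_order <- model$branching_order
  init$growth_mode <- model$growth_mode

  objective <- function(params, run_seed) {
    e <- expected_sfs(params, nh, model = model, n_sims = n_sims,
                      seed = run_seed, exclude_singletons = excl1)
    composite_loglik(obs, e)
  }

  if (length(free) == 0) {
    ll <- objective(init, seed + 1)
    return(structure(list(params = init, loglik = ll, k = 0,
                          AIC = -2 * ll, model = model, runs = NULL,
                          trace = ll, converged = TRUE, n_sims = n_sims,
                          seed = seed),
                     class = "im_fit"))
  }

  best <- NULL
  best_ll <- -Inf
  run_tab <- data.frame(run = integer(), init_ll = numeric(),
                        final_ll = numeric())
  best_trace <- NULL
  for (run in seq_len(n_runs)) {
    run_seed <- seed + 7919 * run
    set.seed(run_seed)
    params <- init
    if (run > 1)
      for (nm in free) {
        b <- bounds[[nm]]
        params <- set_im_par(params, nm,
                             exp(stats::runif(1, log(b[1]), log(b[2]))))
      }
    if (params$T2 >= params$T1)
      params <- set_im_par(params, "T2", params$T1 * 0.5)
    cur_ll <- objective(params, run_seed)
    init_ll <- cur_ll
    trace <- cur_ll
    for (cy in seq_len(cycles)) {
      for (nm in free) {
        b <- bounds[[nm]]
        lo <- log10(b[1]); hi <- log10(b[2])
        if (nm == "T2") hi <- min(hi, log10(params$T1 * 0.95))
        if (nm == "T1") lo <- max(lo, log10(params$T2 / 0.95))
        if (lo >= hi) next
        f1 <- function(lx) {
          -objective(set_im_par(params, nm, 10^lx), run_seed)
        }
        opt <- stats::optimize(f1, c(lo, hi), tol = 0.01)
        if (-opt$objective > cur_ll) {
          params <- set_im_par(params, nm, 10^opt$minimum)
          cur_ll <- -opt$objective
        }
      }
      trace <- c(trace, cur_ll)
    }
    run_tab <- rbind(run_tab, data.frame(run = run, init_ll = init_ll,
                                         final_ll = cur_ll))
    if (cur_ll > best_ll) {
      best_ll <- cur_ll
      best <- params
      best_trace <- trace
    }
  }
  if (polish_sims > n_sims) {
    polish_seed <- seed + 7919 * (n_runs + 1)
    obj2 <- function(params) {
      e <- expected_sfs(params, nh, model = model, n_sims = polish_sims,
                        seed = polish_seed, exclude_singletons = excl1)
      composite_loglik(obs, e)
    }
    cur_ll <- obj2(best)
    for (nm in free) {
      b <- bounds[[nm]]
      lo <- log10(b[1]); hi <- log10(b[2])
      if (nm == "T2") hi <- min(hi, log10(best$T1 * 0.95))
      if (nm == "T1") lo <- max(lo, log10(best$T2 / 0.95))
      if (lo >= hi) next
      opt <- stats::optimize(function(lx) -obj2(set_im_par(best, nm, 10^lx)),
                             c(lo, hi), tol = 0.02)
      if (-opt$objective > cur_ll) {
        best <- set_im_par(best, nm, 10^opt$minimum)
        cur_ll <- -opt$objective
      }
    }
    best_ll <- cur_ll
    best_trace <- c(best_trace, cur_ll)
  }
  converged <- any(run_tab$final_ll > run_tab$init_ll)
  if (!converged)
    warning("no run improved over its starting point; fit flagged")
  k <- length(free)
  structure(list(params = best, loglik = best_ll, k = k,
                 AIC = 2 * k - 2 * best_ll, model = model, runs = run_tab,
                 trace = best_trace, converged = converged,
                 n_sims = n_sims, seed = seed),
            class = "im_fit")
}

#' @export
print.im_fit <- function(x, ...) {
  cat(sprintf("im_fit (%s / %s): composite logL %.2f, k = %d, AIC %.2f%s\n",
              x$model$branching_order, x$model$growth_mode, x$loglik,
              x$k, x$AIC, if (x$converged) "" else " [not converged]"))
  print(x$params)
  invisible(x)
}

#' Fit and compare a set of IM models by Akaike weight
#'
#' Drives \code{\link{fit_im}} over a list of candidate models with the
#' safeguards that matter when models are compared: every model is first
#' fitted cheaply from a common starting point, the best basin found by
#' any model is then used to re-seed and polish the leading candidates,
#' and all final likelihoods are re-evaluated at a common (large)
#' simulation count with common random numbers so that Monte-Carlo error
#' largely cancels from the comparison.
#'
#' @param obs observed \code{\link{folded_sfs}}.
#' @param models named list of \code{\link{model_spec}} objects.
#' @param init common starting \code{\link{im_params}} (also supplies the
#'   fixed parameters).
#' @param n_sims simulation count for the exploratory fits.
#' @param polish_sims simulation count for the polish stage.
#' @param rescore_sims simulation count for the final common-seed
#'   re-evaluation.
#' @param polish_top polish the models within this many log-likelihood
#'   units of the current leader (plus the leader itself).
#' @param cycles exploratory conditional-maximization cycles.
#' @param seed integer seed.
#' @return list with \code{weights} (the \code{\link{akaike_weights}}
#'   table), \code{fits} and \code{rescored} log-likelihoods.
#' @export
compare_im_models <- function(obs, models, init,
                              n_sims = 400, polish_sims = 4000,
                              rescore_sims = 30000, polish_top = 10,
                              cycles = 2, seed = 1) {
  stopifnot(length(models) >= 2)
  nh <- sfs_deme_sizes(obs)
  excl1 <- obs$singletons_excluded > 0
  score <- function(params, model, ns, sc_seed) {
    composite_loglik(obs, expected_sfs(params, nh, model = model,
                                       n_sims = ns, seed = sc_seed,
                                       exclude_singletons = excl1))
  }
  fits <- lapply(models, function(m)
    fit_im(obs, m, init = init, n_runs = 1, cycles = cycles,
           n_sims = n_sims, seed = seed))
  mid <- sapply(names(fits), function(nm)
    score(fits[[nm]]$params, models[[nm]], polish_sims, seed + 101))
  # mutual seeding: refit from the best basin found by any model, then
  # polish the contenders
  best_params <- fits[[which.max(mid)]]$params
  for (nm in names(fits)) {
    cand <- best_params
    cand$branching_order <- models[[nm]]$branching_order
    cand$growth_mode <- models[[nm]]$growth_mode
    if (cand$T2 >= cand$T1) cand$T2 <- cand$T1 * 0.5
    if (score(cand, models[[nm]], polish_sims, seed + 101) > mid[nm])
      fits[[nm]]$params <- cand
  }
  mid <- sapply(names(fits), function(nm)
    score(fits[[nm]]$params, models[[nm]], polish_sims, seed + 101))
  contenders <- names(fits)[mid >= max(mid) - polish_top]
  for (nm in contenders) {
    f2 <- fit_im(obs, models[[nm]], init = fits[[nm]]$params, n_runs = 1,
                 cycles = 1, n_sims = polish_sims, seed = seed + 17)
    if (score(f2$params, models[[nm]], polish_sims, seed + 101) >
        score(fits[[nm]]$params, models[[nm]], polish_sims, seed + 101))
      fits[[nm]]$params <- f2$params
  }
  rescored <- sapply(names(fits), function(nm)
    score(fits[[nm]]$params, models[[nm]], rescore_sims, seed + 999))
  k <- vapply(models, function(m) length(m$free), numeric(1))
  tab <- akaike_weights(data.frame(model = names(fits), logL = rescored,
                                   k = k, stringsAsFactors = FALSE))
  list(weights = tab, fits = fits, rescored = rescored)
}

#' Block-bootstrap confidence intervals over genomic fragments
#'
#' Resamples fragments (linkage blocks of loci) with replacement,
#' re-applies an estimator to each bootstrap genotype matrix, and returns
#' percentile confidence intervals per estimated parameter.
#'
#' @param G a \code{\link{genotype_matrix}} with fragment labels.
#' @param estimator function taking a \code{genotype_matrix} and returning
#'   a named numeric vector.
#' @param n_boot number of bootstrap datasets.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with \code{ci} (data frame: parameter, lower, upper) and
#'   \code{replicates} (bootstrap estimate matrix).
#' @export
block_bootstrap_ci <- function(G, estimator, n_boot = 100, level = 0.95,
                               seed = 1) {
  if (is.null(G$fragments)) stop("genotype matrix carries no fragment labels")
  frags <- unique(G$fragments)
  if (length(frags) < 2) stop("need at least two fragments to resample")
  loci_by_frag <- split(seq_along(G$fragments), G$fragments)
  set.seed(seed)
  reps <- NULL
  for (b in seq_len(n_boot)) {
    pick <- sample(frags, length(frags), replace = TRUE)
    loci <- unlist(loci_by_frag[pick], use.names = FALSE)
    est <- estimator(G[, loci])
    if (is.null(reps)) reps <- matrix(NA_real_, n_boot, length(est),
                                      dimnames = list(NULL, names(est)))
    reps[b, ] <- est
  }
  alpha <- (1 - level) / 2
  ci <- data.frame(parameter = colnames(reps),
                   lower = apply(reps, 2, stats::quantile, alpha,
                                 na.rm = TRUE),
                   upper = apply(reps, 2, stats::quantile, 1 - alpha,
                                 na.rm = TRUE),
                   row.names = NULL, stringsAsFactors = FALSE)
  list(ci = ci, replicates = reps)
}

#' Convert model parameters to absolute units
#'
#' Split times in generations become years via the generation time;
#' mutation-scaled sizes (theta = 4 Ne mu per generation) become diploid
#' effective sizes via the per-generation mutation rate
#' mu_per_year * gen_years.
#'
#' @param times_gen optional vector of times in generations.
#' @param theta optional vector of mutation-scaled sizes (4 Ne mu).
#' @param mu_per_year mutation rate per site per year.
#' @param gen_years generation time in years.
#' @return list with \code{times_years} and/or \code{Ne}.
#' @export
to_absolute_units <- function(times_gen = NULL, theta = NULL,
                              mu_per_year, gen_years) {
  if (mu_per_year <= 0 || gen_years <= 0)
    stop("mutation rate and generation time must be positive")
  out <- list()
  if (!is.null(times_gen)) {
    if (any(times_gen <= 0)) stop("times must be positive")
    out$times_years <- times_gen * gen_years
  }
  if (!is.null(theta)) {
    if (any(theta <= 0)) stop("theta must be positive")
    out$Ne <- theta / (4 * mu_per_year * gen_years)
  }
  out
}

#' Rescale absolute divergence times under different mutation-rate and
#' generation-time assumptions
#'
#' A time estimated in years under (gen_old, mu_old) maps to
#' times * (gen_new / gen_old) * (mu_old / mu_new) under the new
#' constants: the underlying coalescent-scaled quantity is held fixed
#' while the clock is swapped. The transformation is its own inverse when
#' the old and new constants are exchanged.
#'
#' @param times_years_old times (any unit of years) under the old clock.
#' @param gen_old,gen_new generation times in years.
#' @param mu_old,mu_new mutation rates per site per year.
#' @return rescaled times in the same unit.
#' @export
rescale_times <- function(times_years_old, gen_old, mu_old, gen_new,
                          mu_new) {
  if (any(c(times_years_old, gen_old, mu_old, gen_new, mu_new) <= 0))
    stop("all times and rates must be positive")
  times_years_old * (gen_new / gen_old) * (mu_old / mu_new)
}
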