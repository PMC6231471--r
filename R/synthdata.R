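#' Synthetic-dataset configuration
#'
#' Parameters of the synthetic landscape-genomics dataset: a set of
#' populations grouped into clusters, each cluster attached to one of the
#' three demes of an isolation-with-migration model; an environmental
#' gradient over the sampling coordinates; uniform genotype missingness;
#' a minority of environment-associated loci to be spiked; and clustered
#' mitotype pools. Defaults emulate a 17-population, 191-individual,
#' ~4,000-SNP range-wide sample of a wind-pollinated conifer with three
#' major genetic groups plus two micro-refugial single-population
#' clusters.
#'
#' @param pop_names population labels.
#' @param pop_sizes diploid sample size per population.
#' @param cluster_assignment named vector population -> cluster label
#'   (3 to 5 clusters).
#' @param deme_of_cluster named vector cluster -> IM deme ("south",
#'   "north", "west").
#' @param im_params an \code{\link{im_params}} for the deme-level
#'   demography.
#' @param n_loci number of unlinked SNPs.
#' @param missing_rate uniform per-genotype missingness in [0, 1).
#' @param fst_within Balding-Nichols differentiation of populations
#'   around their deme allele frequencies (0 = none).
#' @param n_env number of environmental variables.
#' @param env_slope_x,env_slope_y per-variable gradient slopes over
#'   centered longitude/latitude (recycled).
#' @param env_noise_sd iid noise on each population x variable cell.
#' @param n_adaptive number of loci to spike with an environmental cline.
#' @param adaptive_beta logistic cline slope on the standardized first
#'   environmental variable.
#' @param mito_theta Dirichlet concentration of within-cluster mitotype
#'   pools (small = one dominant mitotype per cluster).
#' @param mito_share probability an individual draws its mitotype from
#'   the range-wide pool instead of its cluster pool.
#' @param loci_per_fragment loci per simulated genomic fragment.
#' @param seed global seed; all stages derive child seeds from it.
#' @return a \code{synth_config} object.
#' @export
synth_config <- function(
    pop_names = c("JL", "NC", "SS", "WT", "LK", "FS", "DS", "TB", "LS",
                  "JZ", "QL", "RG", "HZ", "GY", "NS", "HL", "ZW"),
    pop_sizes = c(10, 11, 12, 11, 12, 12, 12, 9, 12,
                  12, 8, 12, 12, 12, 12, 10, 12),
    cluster_assignment = stats::setNames(
      c(rep("north", 9), rep("west", 4), rep("south", 2), "HL", "ZW"),
      pop_names),
    deme_of_cluster = c(north = "north", west = "west", south = "south",
                        HL = "west", ZW = "north"),
    im_params = divscape::im_params(
      Ne = c(south = 1.09e5, north = 2.1e5, west = 1.27e5),
      Ne_anc1 = 1.5e5, Ne_anc2 = 1.5e5, T1 = 73400, T2 = 11600,
      mig_migrants = 15, branching_order = "south_first"),
    n_loci = 4077, missing_rate = 0.072, fst_within = 0.015,
    n_env = 6, env_slope_x = c(0.5, -0.3, 0.2, 0, 0.4, -0.2),
    env_slope_y = c(1, 0.8, -0.6, 0.9, 0, 0.3),
    env_noise_sd = 0.5,
    n_adaptive = 40, adaptive_beta = 3,
    mito_theta = 0.1, mito_share = 0.02,
    loci_per_fragment = 2, seed = 1) {
  n_pops <- length(pop_names)
  stopifnot(n_pops > 0, length(pop_sizes) == n_pops, all(pop_sizes > 0),
            n_loci > 0, n_env >= 1)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_adaptive > n_loci)
    stop("n_adaptive must not exceed n_loci")
  if (!all(pop_names %in% names(cluster_assignment)))
    stop("cluster_assignment must cover every population")
  clusters <- unique(cluster_assignment[pop_names])
  if (!all(clusters %in% names(deme_of_cluster)))
    stop("deme_of_cluster must cover every cluster")
  if (!all(deme_of_cluster %in% c("south", "north", "west")))
    stop("demes must be south, north or west")
  structure(list(pop_names = pop_names, pop_sizes = pop_sizes,
                 cluster_assignment = cluster_assignment,
                 deme_of_cluster = deme_of_cluster,
                 im_params = im_params, n_loci = n_loci,
                 missing_rate = missing_rate, fst_within = fst_within,
                 n_env = n_env,
                 env_slope_x = rep_len(env_slope_x, n_env),
                 env_slope_y = rep_len(env_slope_y, n_env),
                 env_noise_sd = env_noise_sd,
                 n_adaptive = n_adaptive, adaptive_beta = adaptive_beta,
                 mito_theta = mito_theta, mito_share = mito_share,
                 loci_per_fragment = loci_per_fragment, seed = seed),
            class = "synth_config")
}

# one global seed fans out to independent per-stage child seeds
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^31 - 2, n)
}

cluster_geo_centers <- function(clusters) {
  known <- rbind(north = c(114, 39), west = c(103, 35.5),
                 south = c(107, 33), HL = c(106, 38.7), ZW = c(108.7, 35.6))
  out <- matrix(NA_real_, length(clusters), 2,
                dimnames = list(clusters, c("x", "y")))
  for (cl in clusters) {
    if (cl %in% rownames(known)) out[cl, ] <- known[cl, ]
    else out[cl, ] <- c(stats::runif(1, 100, 120), stats::runif(1, 30, 42))
  }
  out
}

#' Generate a complete synthetic dataset under an IM demography
#'
#' Deme-level haplotypes are simulated with the coalescent
#' isolation-with-migration engine; population allele frequencies are
#' drawn around their deme frequencies by a Balding-Nichols layer
#' (\code{fst_within}) and genotypes sampled binomially; genotype
#' missingness is applied uniformly at random; populations sit on a
#' jittered grid around their cluster's regional center and environmental
#' variables are linear in the centered coordinates plus iid noise;
#' mitotypes are drawn from cluster-specific pools. Deterministic for a
#' fixed seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{synth_bundle}: \code{G} (\code{genotype_matrix}),
#'   \code{popmap}, \code{coords} (pop x 2), \code{env} (pop x vars),
#'   \code{mitotypes}, \code{clustermap} (individual -> cluster) and
#'   \code{truth} (adaptive locus indices, cluster labels, im_params,
#'   deme frequencies).
#' @export
gen_im_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seeds <- child_seeds(config$seed, 6)
  np <- length(config$pop_names)
  cl_of_pop <- config$cluster_assignment[config$pop_names]
  deme_of_pop <- stats::setNames(
    unname(config$deme_of_cluster[cl_of_pop]), config$pop_names)
  clusters <- unique(cl_of_pop)

  # coordinates: jittered grid around cluster centers
  set.seed(seeds[1])
  centers <- cluster_geo_centers(clusters)
  coords <- matrix(NA_real_, np, 2,
                   dimnames = list(config$pop_names, c("x", "y")))
  for (cl in clusters) {
    idx <- which(cl_of_pop == cl)
    k <- length(idx)
    side <- ceiling(sqrt(k))
    gx <- ((seq_len(k) - 1) %% side) - (side - 1) / 2
    gy <- ((seq_len(k) - 1) %/% side) - (side - 1) / 2
    coords[idx, 1] <- centers[cl, 1] + 2.2 * gx + stats::runif(k, -0.9, 0.9)
    coords[idx, 2] <- centers[cl, 2] + 1.6 * gy + stats::runif(k, -0.7, 0.7)
  }

  # environment: linear trend over centered coordinates + noise
  set.seed(seeds[2])
  xc <- coords[, 1] - mean(coords[, 1])
  yc <- coords[, 2] - mean(coords[, 2])
  env <- sapply(seq_len(config$n_env), function(v)
    config$env_slope_x[v] * xc + config$env_slope_y[v] * yc +
      stats::rnorm(np, sd = config$env_noise_sd))
  dimnames(env) <- list(config$pop_names,
                        paste0("env", seq_len(config$n_env)))

  # deme-level coalescent haplotypes -> deme allele frequencies
  n_by_deme <- vapply(c("south", "north", "west"), function(d)
    sum(config$pop_sizes[deme_of_pop == d]), numeric(1))
  sim <- simulate_im(config$im_params, config$n_loci,
                     pmax(n_by_deme, 1), seed = seeds[3],
                     loci_per_fragment = config$loci_per_fragment)
  deme_freq <- rowsum(sim$G$calls + 0,
                      sim$popmap[sim$G$individual_ids]) /
    (2 * as.vector(table(sim$popmap)[sort(unique(sim$popmap))]))

  # population frequencies: Balding-Nichols drift around deme frequency
  set.seed(seeds[4])
  Fw <- config$fst_within
  L <- config$n_loci
  calls <- matrix(NA_integer_, sum(config$pop_sizes), L)
  ids <- character(0)
  row0 <- 0
  pop_freq <- matrix(NA_real_, np, L, dimnames = list(config$pop_names))
  for (i in seq_len(np)) {
    p <- deme_freq[deme_of_pop[i], ]
    if (Fw > 0) {
      inner <- p > 0 & p < 1
      pp <- p
      pp[inner] <- stats::rbeta(sum(inner),
                                p[inner] * (1 - Fw) / Fw,
                                (1 - p[inner]) * (1 - Fw) / Fw)
      p <- pp
    }
    pop_freq[i, ] <- p
    ni <- config$pop_sizes[i]
    calls[row0 + seq_len(ni), ] <-
      matrix(stats::rbinom(ni * L, 2, rep(p, each = ni)), ni, L)
    ids <- c(ids, paste0(config$pop_names[i], ".", seq_len(ni)))
    row0 <- row0 + ni
  }

  # uniform missingness
  set.seed(seeds[5])
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$missing_rate
    calls[mask] <- NA_integer_
  }
  G <- genotype_matrix(calls, individual_ids = ids,
                       locus_ids = paste0("snp", seq_len(L)),
                       fragments = sim$G$fragments)
  popmap <- stats::setNames(rep(config$pop_names, config$pop_sizes), ids)
  clustermap <- stats::setNames(cl_of_pop[popmap], ids)

  # mitotypes: cluster pools named after the range-wide mitotype alphabet
  pools <- split(paste0("M", seq_len(2 * length(clusters))),
                 rep(clusters, each = 2))
  mito <- gen_mitotypes(clustermap, pools, theta = config$mito_theta,
                        share = config$mito_share, seed = seeds[6])

  structure(list(G = G, popmap = popmap, coords = coords, env = env,
                 mitotypes = mito, clustermap = clustermap,
                 config = config,
                 truth = list(adaptive = integer(0), beta = NA_real_,
                              cluster = cl_of_pop,
                              deme_of_pop = deme_of_pop,
                              im_params = config$im_params,
                              pop_freq = pop_freq)),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synth_bundle: %d populations in %d clusters, %d individuals x %d loci\n",
              length(x$config$pop_names),
              length(unique(x$config$cluster_assignment)),
              nrow(x$G$calls), ncol(x$G$calls)))
  cat(sprintf("  %d spiked adaptive loci\n", length(x$truth$adaptive)))
  invisible(x)
}

#' Spike environment-associated loci into a synthetic bundle
#'
#' For n chosen loci, population allele frequencies are replaced by a
#' logistic cline on the standardized first environmental variable,
#' logistic(logit(p0) + beta z_env), and genotypes redrawn binomially
#' (the missingness pattern is preserved). Truth records are updated.
#'
#' @param bundle a \code{synth_bundle}.
#' @param beta logistic cline slope (0 = null).
#' @param n number of loci to spike.
#' @param seed integer seed.
#' @return the modified \code{synth_bundle}.
#' @export
spike_adaptive_loci <- function(bundle, beta = NULL, n = NULL, seed = 1) {
  stopifnot(inherits(bundle, "synth_bundle"))
  beta <- beta %||% bundle$config$adaptive_beta
  n <- n %||% bundle$config$n_adaptive
  L <- ncol(bundle$G$calls)
  if (n > L) stop("cannot spike more loci than exist")
  if (is.null(bundle$env) || ncol(bundle$env) < 1)
    stop("bundle carries no environmental variables")
  set.seed(seed)
  pooled <- colMeans(bundle$G$calls, na.rm = TRUE) / 2
  eligible <- which(pooled >= 0.1 & pooled <= 0.9)
  if (length(eligible) < n) eligible <- seq_len(L)
  target <- sort(sample(eligible, n))
  z <- as.vector(scale(bundle$env[, 1]))
  names(z) <- rownames(bundle$env)
  calls <- bundle$G$calls
  pops <- bundle$popmap[bundle$G$individual_ids]
  for (l in target) {
    p0 <- min(max(pooled[l], 0.05), 0.95)
    p_pop <- stats::plogis(stats::qlogis(p0) + beta * z)
    bundle$truth$pop_freq[, l] <- p_pop
    for (pn in rownames(bundle$env)) {
      rows <- which(pops == pn)
      keep_na <- is.na(calls[rows, l])
      calls[rows, l] <- stats::rbinom(length(rows), 2, p_pop[pn])
      calls[rows, l][keep_na] <- NA_integer_
    }
  }
  bundle$G <- genotype_matrix(calls,
                              individual_ids = bundle$G$individual_ids,
                              locus_ids = bundle$G$locus_ids,
                              fragments = bundle$G$fragments)
  bundle$truth$adaptive <- sort(union(bundle$truth$adaptive, target))
  bundle$truth$beta <- beta
  bundle
}

#' Generate clustered mitotypes
#'
#' Each cluster owns a haplotype pool with Dirichlet(theta) frequencies
#' (small theta concentrates the pool on one dominant mitotype, producing
#' strong among-cluster structure); individuals draw from their cluster
#' pool, or with probability \code{share} from the pooled range-wide
#' alphabet (rare cross-cluster sharing).
#'
#' @param groupmap named vector individual -> cluster.
#' @param refugium_map named list cluster -> character vector of
#'   haplotype labels (each non-empty).
#' @param theta Dirichlet concentration within pools.
#' @param share cross-cluster sharing probability.
#' @param seed integer seed.
#' @return named character vector individual -> mitotype.
#' @export
gen_mitotypes <- function(groupmap, refugium_map, theta = 0.1,
                          share = 0.02, seed = 1) {
  groups <- unique(groupmap)
  if (!all(groups %in% names(refugium_map)))
    stop("refugium_map must assign a pool to every cluster")
  if (any(vapply(refugium_map[groups], length, integer(1)) == 0))
    stop("empty haplotype pool")
  set.seed(seed)
  weights <- lapply(refugium_map[groups], function(pool) {
    w <- stats::rgamma(length(pool), shape = theta)
    if (sum(w) == 0) w <- rep(1, length(pool))
    stats::setNames(w / sum(w), pool)
  })
  names(weights) <- groups
  all_h <- unique(unlist(refugium_map[groups]))
  out <- character(length(groupmap))
  for (i in seq_along(groupmap)) {
    if (share > 0 && stats::runif(1) < share) {
      out[i] <- sample(all_h, 1)
    } else {
      w <- weights[[groupmap[i]]]
      out[i] <- sample(names(w), 1, prob = w)
    }
  }
  stats::setNames(out, names(groupmap))
}

#' Generate niche occurrence/background samples and suitability grids
#'
#' Occurrences are drawn around per-group environmental (and geographic)
#' centers; each group's background points come from a wider envelope
#' containing the occurrences (3x the occurrence spread) whose center is
#' pulled toward the range-wide mean by \code{bg_attenuation} — occupied
#' niches are environmentally more extreme than the background regions
#' they sit in, which is what makes observed niche divergence exceed
#' background divergence. Suitability grids are normalized kernel
#' densities of the occurrence coordinates on a shared extent.
#'
#' @param centers groups x variables matrix of environmental means
#'   (>= 2 variables); row names are group labels.
#' @param spread within-group standard deviation (environment).
#' @param bg_attenuation fraction of a group's environmental offset from
#'   the pooled mean retained by its background region (0 = identical
#'   backgrounds, 1 = backgrounds as divergent as the niches).
#' @param n_occ occurrences per group (>= 4).
#' @param n_bg background points per group.
#' @param grid_shape suitability grid resolution.
#' @param geo_centers optional groups x 2 matrix of geographic centers;
#'   defaults to equally spaced locations.
#' @param geo_spread within-group geographic standard deviation.
#' @param seed integer seed.
#' @return list with \code{samples} (list of \code{\link{niche_sample}}),
#'   \code{grids} (list of normalized suitability matrices).
#' @export
gen_niche_points <- function(centers, spread = 1, n_occ = 50,
                             n_bg = 1000, grid_shape = c(50, 50),
                             geo_centers = NULL, geo_spread = 0.8,
                             bg_attenuation = 0.2, seed = 1) {
  centers <- as.matrix(centers)
  if (ncol(centers) < 2) stop("need at least two environmental variables")
  if (n_occ < 4) stop("need at least 4 occurrences per group")
  groups <- rownames(centers) %||% paste0("g", seq_len(nrow(centers)))
  if (is.null(geo_centers))
    geo_centers <- cbind(x = 5 * seq_len(nrow(centers)),
                         y = rep(0, nrow(centers)))
  set.seed(seed)
  vnames <- colnames(centers) %||% paste0("env", seq_len(ncol(centers)))
  samples <- list()
  grids <- list()
  all_xy <- NULL
  pooled <- colMeans(centers)
  for (g in seq_len(nrow(centers))) {
    bg_center <- pooled + bg_attenuation * (centers[g, ] - pooled)
    occ_env <- sapply(seq_len(ncol(centers)), function(v)
      stats::rnorm(n_occ, centers[g, v], spread))
    bg_env <- sapply(seq_len(ncol(centers)), function(v)
      stats::rnorm(n_bg, bg_center[v], 3 * spread))
    occ_xy <- cbind(stats::rnorm(n_occ, geo_centers[g, 1], geo_spread),
                    stats::rnorm(n_occ, geo_centers[g, 2], geo_spread))
    bg_xy <- cbind(stats::rnorm(n_bg, geo_centers[g, 1], 3 * geo_spread),
                   stats::rnorm(n_bg, geo_centers[g, 2], 3 * geo_spread))
    occ <- data.frame(x = occ_xy[, 1], y = occ_xy[, 2], occ_env)
    bg <- data.frame(x = bg_xy[, 1], y = bg_xy[, 2], bg_env)
    colnames(occ) <- colnames(bg) <- c("x", "y", vnames)
    samples[[groups[g]]] <- niche_sample(occ, bg, group = groups[g])
    all_xy <- rbind(all_xy, occ_xy, bg_xy)
  }
  padx <- 0.05 * diff(range(all_xy[, 1]))
  pady <- 0.05 * diff(range(all_xy[, 2]))
  lims <- c(range(all_xy[, 1]) + c(-padx, padx),
            range(all_xy[, 2]) + c(-pady, pady))
  for (g in groups)
    grids[[g]] <- kde_suitability(samples[[g]]$occ, grid_shape, lims)
  list(samples = samples, grids = grids)
}
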