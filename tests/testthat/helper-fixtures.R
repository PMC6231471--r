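# shared fixtures, all generated in code

# a small deterministic genotype matrix with depth/quality layers
toy_genotypes <- function(seed = 1, n_ind = 8, n_loci = 10) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), n_ind * n_loci, replace = TRUE,
                         prob = c(0.45, 0.25, 0.25, 0.05)),
                  n_ind, n_loci)
  depth <- matrix(sample(3:60, n_ind * n_loci, replace = TRUE),
                  n_ind, n_loci)
  gq <- matrix(sample(5:60, n_ind * n_loci, replace = TRUE),
               n_ind, n_loci)
  genotype_matrix(calls, depth = depth, gq = gq,
                  fragments = paste0("f", (seq_len(n_loci) + 1) %/% 2))
}

toy_popmap <- function(G, n_pops = 2) {
  stats::setNames(rep(paste0("pop", seq_len(n_pops)),
                      length.out = nrow(G$calls)),
                  G$individual_ids)
}

# a small 9-population 3-cluster configuration for fast pipeline tests
tiny_config <- function(n_loci = 400, seed = 1, n_adaptive = 0, ...) {
  pops <- paste0("P", 1:9)
  synth_config(
    pop_names = pops, pop_sizes = rep(8, 9),
    cluster_assignment = stats::setNames(
      rep(c("north", "west", "south"), each = 3), pops),
    deme_of_cluster = c(north = "north", west = "west", south = "south"),
    n_loci = n_loci, n_adaptive = n_adaptive, seed = seed, ...)
}

# study-condition IM parameters (Fig 2-scale values)
study_params <- function() {
  M <- matrix(0, 3, 3)
  M[1, 3] <- M[3, 1] <- 19   # south-west
  M[2, 3] <- M[3, 2] <- 14   # north-west
  M[1, 2] <- M[2, 1] <- 2    # south-north
  im_params(Ne = c(1.09e5, 2.1e5, 1.27e5), Ne_anc1 = 1.5e5,
            Ne_anc2 = 1.5e5, T1 = 73400, T2 = 11600,
            mig_migrants = M, branching_order = "south_first")
}

# independent Weir-Cockerham (1984) variance components, written term by
# term per locus from the published formulas (oracle for wc_fst)
wc_oracle_locus <- function(dosages_by_pop) {
  dat <- dosages_by_pop[vapply(dosages_by_pop, function(x)
    sum(!is.na(x)) > 0, logical(1))]
  r <- length(dat)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  n_i <- vapply(dat, function(x) sum(!is.na(x)), numeric(1))
  p_i <- vapply(dat, function(x) sum(x, na.rm = TRUE), numeric(1)) /
    (2 * n_i)
  h_i <- vapply(dat, function(x) mean(x[!is.na(x)] == 1), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# exact permutation t-test by full enumeration of label assignments
perm_t_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  tstat <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
    if (!is.finite(sp) || sp < 1e-15) sp <- 1e-15
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  t_obs <- abs(tstat(a, b))
  splits <- utils::combn(length(pooled), n1)
  ts <- apply(splits, 2, function(idx)
    abs(tstat(pooled[idx], pooled[-idx])))
  mean(ts >= t_obs - 1e-12)
}
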