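test_that("IM parameter validation rejects impossible topologies", {
  expect_error(im_params(T1 = 100, T2 = 200), "topology")
  expect_error(im_params(T1 = 100, T2 = 100), "topology")
  expect_error(im_params(Ne = c(0, 1, 1) * 1e4), "sizes")
  expect_silent(im_params(T1 = Inf, T2 = Inf))
  expect_length(all_im_models(), 9)
})

test_that("simulation is deterministic per seed and missing-free", {
  p <- im_params(Ne = c(1e4, 1e4, 1e4), T1 = 8000, T2 = 2000, mig = 1e-4)
  s1 <- simulate_im(p, 60, c(4, 4, 4), seed = 3)
  s2 <- simulate_im(p, 60, c(4, 4, 4), seed = 3)
  expect_identical(s1, s2)
  expect_false(anyNA(s1$G$calls))
  s3 <- simulate_im(p, 60, c(4, 4, 4), seed = 4)
  expect_false(identical(s1$G$calls, s3$G$calls))
  # every site segregating
  pooled <- colMeans(s1$G$calls) / 2
  expect_true(all(pooled > 0 & pooled < 1))
})

test_that("single-population heterozygosity matches the Watterson-weighted closed form", {
  # sites fall on genealogy branches with probability proportional to
  # expected length: derived count i has weight 1/i; with paired haploids,
  # E[observed het] per segregating site is sum w_i 2i(K-i)/(K(K-1))
  K <- 16
  w <- (1 / (1:(K - 1)))
  w <- w / sum(w)
  e_het <- sum(w * 2 * (1:(K - 1)) * (K - 1:(K - 1)) / (K * (K - 1)))
  p <- im_params(Ne = c(1e4, 1e4, 1e4), T1 = Inf, T2 = Inf)
  hets <- replicate(6, {
    sim <- simulate_im(p, 600, c(K / 2, 0, 0),
                       seed = sample.int(1e6, 1))
    mean(colMeans(sim$G$calls == 1))
  })
  se <- stats::sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - e_het), 3 * se + 1e-8)
})

test_that("two isolated populations match an independent msprime oracle", {
  # the same demography simulated by msprime (independent coalescent
  # engine); mean Weir-Cockerham FST of the two simulators must agree
  py <- file.path(tempdir(), "msp_oracle.py")
  out_csv <- file.path(tempdir(), "msp_fst_geno.csv")
  writeLines(c(
    "import msprime, numpy as np, sys",
    "dem = msprime.Demography()",
    "dem.add_population(name='A', initial_size=1e4)",
    "dem.add_population(name='B', initial_size=1e4)",
    "dem.add_population(name='anc', initial_size=1e4)",
    "dem.add_population_split(time=4000, derived=['A','B'], ancestral='anc')",
    "rng = np.random.default_rng(int(sys.argv[1]))",
    "geno = []",
    "reps = msprime.sim_ancestry(samples={'A':8,'B':8}, demography=dem,",
    "    num_replicates=1500, random_seed=int(sys.argv[1]))",
    "for ts in reps:",
    "    t = ts.first()",
    "    nodes = [u for u in t.nodes() if t.parent(u) != -1]",
    "    lens = np.array([t.branch_length(u) for u in nodes])",
    "    u = rng.choice(len(nodes), p=lens/lens.sum())",
    "    der = set(t.leaves(nodes[u]))",
    "    h = np.array([1 if i in der else 0 for i in range(32)])",
    "    geno.append(h[0::2] + h[1::2])",
    "np.savetxt(sys.argv[2], np.array(geno).T, fmt='%d', delimiter=',')"),
    py)
  # note: msprime draws one mutation per genealogy (unweighted by length);
  # compare both engines under matched per-genealogy conditioning
  res <- system2("python", c(py, "11", out_csv), stdout = TRUE,
                 stderr = TRUE)
  expect_true(file.exists(out_csv))
  gm <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  Gm <- genotype_matrix(gm)
  fst_msp <- wc_fst(Gm, stats::setNames(rep(c("A", "B"), each = 8),
                                        Gm$individual_ids))$theta

  p <- im_params(Ne = c(1e4, 1e4, 1e4), Ne_anc1 = 1e4, Ne_anc2 = 1e4,
                 T1 = Inf, T2 = 4000, mig = 0,
                 branching_order = "south_first")
  fst_mine <- sapply(1:4, function(s) {
    sim <- simulate_im(p, 1500, c(0, 8, 8), seed = s)
    wc_fst(sim$G, sim$popmap)$theta
  })
  se <- stats::sd(fst_mine) / sqrt(4)
  # allow 3 SE of the replicate spread plus the oracle's own noise
  expect_lt(abs(mean(fst_mine) - fst_msp), 3 * se + 0.03)
})

test_that("hypergeometric projection matches exact enumeration and direct counting", {
  # single SNP: pop of 4 haploids with 2 alt, projected to 2
  calls <- matrix(c(1L, 1L), 2, 1)  # two heterozygotes = 2 alt in 4 alleles
  G <- genotype_matrix(calls)
  obs <- project_folded_sfs(G, stats::setNames(c("A", "A"),
                                               G$individual_ids), c(A = 2))
  # exact: P(j alt of 2 | 2 of 4) = choose(2,j) choose(2,2-j) / choose(4,2)
  exact <- c(choose(2, 0) * choose(2, 2), choose(2, 1) * choose(2, 1),
             choose(2, 2) * choose(2, 0)) / choose(4, 2)
  # folded with monomorphic mass excluded: cell 1 keeps exact[2];
  # cells 0 and 2 are monomorphic and excluded
  expect_equal(unname(obs$entries[2]), exact[2])
  expect_equal(obs$monomorphic_excluded, exact[1] + exact[3])

  # projection to the observed size with no missing data = direct counting
  set.seed(2)
  calls2 <- matrix(rbinom(8 * 30, 2, 0.4), 8, 30)
  G2 <- genotype_matrix(calls2)
  pm <- stats::setNames(rep(c("north", "west"), each = 4),
                        G2$individual_ids)
  obs2 <- project_folded_sfs(G2, pm, c(north = 8, west = 8))
  direct <- array(0, c(9, 9))
  for (l in 1:30) {
    d1 <- sum(calls2[1:4, l])
    d2 <- sum(calls2[5:8, l])
    direct[d1 + 1, d2 + 1] <- direct[d1 + 1, d2 + 1] + 1
  }
  direct[1, 1] <- 0; direct[9, 9] <- 0
  folded_direct <- divscape:::fold_array(direct)
  expect_equal(unclass(obs2$entries), folded_direct, tolerance = 1e-12)
  expect_error(project_folded_sfs(G2, pm, c(north = 0, west = 8)),
               "positive")
})

test_that("folding obeys the one-dimensional identity with half-weight ties", {
  u <- c(0, 5, 4, 3, 2, 1, 0.5, 0.25, 0)  # unfolded counts, n = 8
  f <- divscape:::fold_array(array(u, 9))
  expect_equal(f[2], u[2] + u[8])
  expect_equal(f[3], u[3] + u[7])
  expect_equal(f[4], u[4] + u[6])
  expect_equal(f[5], u[5])        # i = n/2 kept once
  expect_equal(sum(f), sum(u))    # mass conserved
  expect_true(all(f[6:9] == 0))
})

test_that("expected SFS matches the Watterson closed form and is symmetric", {
  p <- im_params(Ne = c(1e4, 1e4, 1e4), T1 = Inf, T2 = Inf)
  n <- 8
  th <- sapply(1:(n / 2), function(i)
    1 / i + ifelse(i < n - i, 1 / (n - i), 0))
  th <- th / sum(th)
  reps <- sapply(1:12, function(s)
    expected_sfs(p, c(n, 0, 0), n_sims = 8000, seed = s)$entries[2:5])
  se <- apply(reps, 1, stats::sd) / sqrt(12)
  # 3.5 SE per cell: the 3-SE band with an allowance for testing four
  # (correlated) cells jointly
  expect_true(all(abs(rowMeans(reps) - th) < 3.5 * se + 1e-6))

  # label-exchangeable populations -> symmetric joint spectrum
  p2 <- im_params(Ne = c(1e4, 1e4, 1e4), Ne_anc1 = 1e4, Ne_anc2 = 1e4,
                  T1 = Inf, T2 = 3000, mig = 0,
                  branching_order = "south_first")
  ea <- divscape:::engine_args(p2)
  set.seed(5)
  arr <- divscape:::cpp_branch_sfs(c(0L, 6L, 6L), ea$f, ea$T1, ea$T2,
                                   ea$Ne, ea$Ne_anc1, ea$Ne_anc2, ea$r,
                                   ea$t_end, ea$mig, 30000L)
  m <- array(arr, c(7, 7))  # unfolded joint branch lengths, pops 2 and 3
  m <- m / sum(m)
  expect_lt(max(abs(m - t(m))), 0.02)
})

test_that("composite log-likelihood has its closed forms and maxima", {
  # uniform expected over C cells -> logL = n log(1/C)
  dims <- c(4L)
  mask <- divscape:::sfs_cell_mask(dims + 1L)
  C <- sum(mask)
  e_entries <- array(0, dims + 1L)
  e_entries[mask] <- 1 / C
  e <- folded_sfs(e_entries, dims, normalized = TRUE, n_sims = 1e6)
  o_entries <- array(0, dims + 1L)
  o_entries[mask] <- c(30, 70)
  o <- folded_sfs(o_entries, dims)
  expect_equal(composite_loglik(o, e), 100 * log(1 / C))

  # for fixed obs, the maximizing expected distribution is obs/n: verify
  # by exhaustive grid over the 2-cell simplex
  grid <- seq(0.01, 0.99, by = 0.01)
  lls <- sapply(grid, function(q) {
    ee <- array(0, dims + 1L)
    ee[mask] <- c(q, 1 - q)
    composite_loglik(o, folded_sfs(ee, dims, normalized = TRUE,
                                   n_sims = 1e6))
  })
  expect_equal(grid[which.max(lls)], 0.3)
  expect_error(composite_loglik(o, folded_sfs(array(1, 6), 5L,
                                              normalized = TRUE)),
               "dimensions")
})

test_that("Akaike weights follow the closed forms", {
  f <- data.frame(logL = c(-100, -100, -100), k = c(3, 3, 3))
  w <- akaike_weights(f)
  expect_equal(w$weight, rep(1 / 3, 3))
  w2 <- akaike_weights(data.frame(logL = c(-100, -101), k = c(3, 3)))
  expect_equal(w2$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  w3 <- akaike_weights(data.frame(logL = c(-100, -125), k = c(3, 3)))
  expect_gt(w3$weight[1], 0.999)
  expect_equal(sum(w3$weight), 1)
  expect_error(akaike_weights(data.frame(logL = -1, k = 1)), "two")
})

test_that("fitting with no free parameters returns the initial likelihood", {
  p <- im_params(Ne = c(1e4, 1e4, 1e4), Ne_anc1 = 1e4, Ne_anc2 = 1e4,
                 T1 = 8000, T2 = 2000, mig = 0)
  sim <- simulate_im(p, 300, c(4, 4, 4), seed = 2)
  obs <- project_folded_sfs(sim$G, sim$popmap,
                            c(south = 8, north = 8, west = 8))
  m0 <- model_spec("south_first", "constant", free = character(0))
  fit <- fit_im(obs, m0, init = p, n_sims = 300, seed = 9)
  expect_equal(fit$k, 0)
  expect_identical(fit$params$T2, p$T2)
  expect_true(is.finite(fit$loglik))
})

test_that("a single free split time is recovered from two-population data", {
  p <- im_params(Ne = c(1e4, 1e4, 1e4), Ne_anc1 = 1e4, Ne_anc2 = 1e4,
                 T1 = 1e9, T2 = 8000, mig = 0,
                 branching_order = "south_first")
  sim <- simulate_im(p, 3000, c(0, 10, 10), seed = 5)
  obs <- project_folded_sfs(sim$G, sim$popmap, c(north = 10, west = 10))
  m1 <- model_spec("south_first", "constant", free = "T2")
  fit <- fit_im(obs, m1, init = p, n_runs = 1, cycles = 3, n_sims = 800,
                polish_sims = 4000, seed = 3)
  expect_lt(abs(log(fit$params$T2 / 8000)), log(1.25))
  # within-run likelihood trace is monotone non-decreasing
  expect_true(all(diff(fit$trace) >= -1e-9))
})

test_that("block bootstrap honors fragments, seeds and degenerate cases", {
  G <- toy_genotypes(seed = 21, n_ind = 10, n_loci = 20)
  # identical fragments: duplicate one fragment everywhere
  Gd <- G
  Gd$calls <- G$calls[, rep(1:2, 10)]
  colnames(Gd$calls) <- make.unique(colnames(Gd$calls))
  Gd <- genotype_matrix(Gd$calls, fragments = rep(paste0("f", 1:10),
                                                  each = 2))
  same <- function(g) c(m = mean(g$calls, na.rm = TRUE))
  ci <- block_bootstrap_ci(Gd, same, n_boot = 20, seed = 1)$ci
  expect_equal(ci$lower, ci$upper)

  est <- function(g) c(m = mean(g$calls, na.rm = TRUE))
  b1 <- block_bootstrap_ci(G, est, n_boot = 15, seed = 7)
  b2 <- block_bootstrap_ci(G, est, n_boot = 15, seed = 7)
  expect_identical(b1$ci, b2$ci)
  G_nofrag <- genotype_matrix(G$calls)
  expect_error(block_bootstrap_ci(G_nofrag, est), "fragment")
})

test_that("block-bootstrap CIs cover the truth at close to nominal rate", {
  # blocks of iid loci; estimator = mean dosage; true mean known
  set.seed(99)
  cover <- replicate(120, {
    calls <- matrix(rbinom(6 * 40, 2, 0.3), 6, 40)
    G <- genotype_matrix(calls, fragments = rep(paste0("f", 1:10),
                                                each = 4))
    ci <- block_bootstrap_ci(G, function(g)
      c(m = mean(g$calls)), n_boot = 60,
      seed = sample.int(1e6, 1))$ci
    ci$lower <= 0.6 && 0.6 <= ci$upper
  })
  expect_gt(mean(cover), 0.85)
})

test_that("unit conversion and time rescaling reproduce the published arithmetic", {
  expect_equal(round(rescale_times(3.67, 50, 7e-10, 20, 13.1e-10), 2),
               0.78)
  expect_equal(round(rescale_times(0.58, 50, 7e-10, 20, 13.1e-10), 2),
               0.12)
  expect_equal(rescale_times(5, 50, 7e-10, 50, 7e-10), 5)
  # swapping old and new constants inverts the transformation
  once <- rescale_times(3.67, 50, 7e-10, 20, 13.1e-10)
  expect_equal(rescale_times(once, 20, 13.1e-10, 50, 7e-10), 3.67)
  expect_error(rescale_times(-1, 50, 7e-10, 20, 13.1e-10), "positive")

  abs_units <- to_absolute_units(times_gen = c(73400, 11600),
                                 theta = 4 * 2.1e5 * 3.5e-8,
                                 mu_per_year = 7e-10, gen_years = 50)
  expect_equal(abs_units$times_years, c(3.67e6, 5.8e5))
  expect_equal(abs_units$Ne, 2.1e5)
  expect_error(to_absolute_units(times_gen = 1, mu_per_year = 0,
                                 gen_years = 50), "positive")
})

test_that("divergence times are recent on the coalescent timescale", {
  # the fitted-scale parameters put both splits well under one Ne
  # generation, the regime the low observed differentiation reflects
  p <- study_params()
  ratios <- c(p$T1 / p$Ne, p$T2 / p$Ne)
  expect_true(all(ratios > 0.05 & ratios < 0.8))
})
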