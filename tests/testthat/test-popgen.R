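test_that("genotype masking matches an exhaustive cell-wise check", {
  G <- toy_genotypes(seed = 3, n_ind = 3, n_loci = 3)
  masked <- mask_genotypes(G, gq_min = 20, dp_min = 5)
  for (i in 1:3) for (j in 1:3) {
    should_mask <- (!is.na(G$gq[i, j]) && G$gq[i, j] < 20) ||
      (!is.na(G$depth[i, j]) && G$depth[i, j] < 5)
    if (should_mask) expect_true(is.na(masked$calls[i, j]))
    else expect_identical(masked$calls[i, j], G$calls[i, j])
  }
  # no locus removed
  expect_identical(dim(masked$calls), dim(G$calls))

  # all above thresholds -> unchanged; single low-depth cell -> that cell
  G2 <- genotype_matrix(matrix(1L, 2, 2), depth = matrix(50, 2, 2),
                        gq = matrix(50, 2, 2))
  expect_identical(mask_genotypes(G2)$calls, G2$calls)
  G2$depth[1, 2] <- 4
  m2 <- mask_genotypes(G2)
  expect_true(is.na(m2$calls[1, 2]))
  expect_equal(sum(is.na(m2$calls)), 1)

  # no layers -> identity with warning
  G3 <- genotype_matrix(matrix(1L, 2, 2))
  expect_warning(m3 <- mask_genotypes(G3), "unmasked")
  expect_identical(m3$calls, G3$calls)
})

test_that("locus filtering matches brute-force rule evaluation and is idempotent", {
  # hand-set 10-locus panel with known violations across two populations
  set.seed(7)
  calls <- matrix(1L, 10, 10)
  calls[, 1] <- c(rep(0L, 9), 1L)              # MAF 0.05 -> kept (not < 0.05)
  calls[, 2] <- c(rep(0L, 19 %/% 2), 1L)[1:10] # recompute below
  calls[, 2] <- c(rep(0L, 10))                 # monomorphic -> maf 0 dropped
  calls[, 3] <- c(1L, 1L, 1L, 1L, NA, NA, NA, 0L, 0L, 2L)  # 30% missing
  calls[, 4] <- rep(1L, 10)                    # all het -> het rule
  calls[, 5] <- c(0L, 0L, 2L, 2L, 0L, 2L, 0L, 2L, 0L, 2L)
  calls[, 6] <- c(0L, 1L, 2L, NA, NA, 0L, 1L, 2L, 0L, 1L)  # pop1 3 genotyped
  calls[, 7:10] <- matrix(sample(0:2, 40, TRUE), 10, 4)
  G <- genotype_matrix(calls)
  popmap <- stats::setNames(rep(c("A", "B"), each = 5), G$individual_ids)
  spec <- filter_spec(maf_min = 0.05, missing_rate_max = 0.3,
                      het_max = 0.5, min_genotyped_per_pop = 4)
  res <- filter_loci(G, spec, popmap)

  # brute-force evaluation of every rule
  brute_keep <- vapply(seq_len(ncol(calls)), function(l) {
    g <- calls[, l]
    ok <- !is.na(g)
    p <- sum(g[ok]) / (2 * sum(ok))
    if (min(p, 1 - p) < 0.05) return(FALSE)
    if (mean(!ok) >= 0.3) return(FALSE)
    if (mean(g[ok] == 1) > 0.5) return(FALSE)
    for (pp in unique(popmap))
      if (sum(ok[popmap == pp]) < 4) return(FALSE)
    TRUE
  }, logical(1))
  expect_identical(res$G$locus_ids, G$locus_ids[brute_keep])
  expect_setequal(res$rejected$locus_id, G$locus_ids[!brute_keep])

  # first-failing-rule reasons for the constructed violations
  reasons <- stats::setNames(res$rejected$rule, res$rejected$locus_id)
  expect_identical(unname(reasons["locus2"]), "maf")
  expect_identical(unname(reasons["locus4"]), "het")
  expect_identical(unname(reasons["locus6"]), "min_per_pop")

  # idempotence
  res2 <- filter_loci(res$G, spec, popmap)
  expect_identical(res2$G$calls, res$G$calls)
  expect_equal(nrow(res2$rejected), 0)
})

test_that("population allele frequencies equal direct counting", {
  G <- genotype_matrix(rbind(c(0L, NA), c(2L, NA)))
  pf <- pop_allele_freqs(G, stats::setNames(c("A", "A"), G$individual_ids))
  expect_equal(unname(pf$freq[1, 1]), 0.5)
  expect_true(pf$flagged[1, 2])
  expect_true(is.na(pf$freq[1, 2]))

  G2 <- toy_genotypes(seed = 11, n_ind = 9, n_loci = 12)
  popmap <- toy_popmap(G2, 3)
  pf2 <- pop_allele_freqs(G2, popmap)
  for (p in unique(popmap)) for (l in seq_len(12)) {
    g <- G2$calls[popmap == p, l]
    ok <- !is.na(g)
    expected <- if (sum(ok) == 0) NA_real_ else sum(g[ok]) / (2 * sum(ok))
    expect_equal(unname(pf2$freq[p, l]), expected)
  }
})

test_that("diversity summary equals direct enumeration", {
  # monomorphic population and fully heterozygous population
  calls <- rbind(matrix(0L, 4, 5), matrix(1L, 4, 5))
  G <- genotype_matrix(calls)
  popmap <- stats::setNames(rep(c("mono", "het"), each = 4),
                            G$individual_ids)
  d <- diversity_summary(G, popmap)
  expect_equal(d$pct_poly[d$population == "mono"], 0)
  expect_equal(d$het[d$population == "mono"], 0)
  expect_equal(d$het[d$population == "het"], 1)
  # expected-heterozygosity switch: all-het population has p = 0.5, so
  # unbiased He = 2n/(2n-1) * 0.5 with n = 4 diploids
  de <- diversity_summary(G, popmap, type = "expected")
  expect_equal(de$het[de$population == "het"], 8 / 7 * 0.5)
  expect_equal(de$het[de$population == "mono"], 0)

  G2 <- toy_genotypes(seed = 5, n_ind = 10, n_loci = 15)
  popmap2 <- toy_popmap(G2, 2)
  d2 <- diversity_summary(G2, popmap2)
  for (p in unique(popmap2)) {
    sub <- G2$calls[popmap2 == p, ]
    poly <- het <- numeric(0)
    for (l in seq_len(ncol(sub))) {
      g <- sub[!is.na(sub[, l]), l]
      if (length(g) == 0) next
      poly <- c(poly, any(g > 0) && any(g < 2))
      het <- c(het, mean(g == 1))
    }
    expect_equal(d2$pct_poly[d2$population == p], 100 * mean(poly))
    expect_equal(d2$het[d2$population == p], mean(het))
  }
})

test_that("Weir-Cockerham FST matches the term-wise oracle on a printed toy", {
  # 2 pops x 4 diploids x 3 loci, dosages enumerated
  calls <- rbind(
    c(0L, 1L, 2L), c(0L, 1L, 1L), c(1L, 0L, 2L), c(0L, 2L, 2L),  # pop A
    c(2L, 1L, 0L), c(2L, 0L, 0L), c(1L, 1L, 1L), c(2L, NA, 0L))  # pop B
  G <- genotype_matrix(calls)
  popmap <- stats::setNames(rep(c("A", "B"), each = 4), G$individual_ids)
  res <- wc_fst(G, popmap)
  for (l in 1:3) {
    o <- wc_oracle_locus(list(calls[1:4, l], calls[5:8, l]))
    expect_equal(res$per_locus$a[l], unname(o["a"]), tolerance = 1e-12)
    expect_equal(res$per_locus$b[l], unname(o["b"]), tolerance = 1e-12)
    expect_equal(res$per_locus$c[l], unname(o["c"]), tolerance = 1e-12)
  }
  abc <- t(sapply(1:3, function(l)
    wc_oracle_locus(list(calls[1:4, l], calls[5:8, l]))))
  expect_equal(res$theta, sum(abc[, 1]) / sum(rowSums(abc)),
               tolerance = 1e-12)
})

test_that("FST is 1 for fixed differences and near 0 under panmixia", {
  calls <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  G <- genotype_matrix(calls)
  popmap <- stats::setNames(rep(c("A", "B"), each = 4), G$individual_ids)
  expect_equal(wc_fst(G, popmap)$theta, 1)

  # panmixia: mean theta over replicates within 3 SE of 0
  set.seed(42)
  thetas <- replicate(50, {
    p <- runif(40, 0.1, 0.9)
    calls <- sapply(p, function(pp) rbinom(16, 2, pp))
    G <- genotype_matrix(calls)
    wc_fst(G, stats::setNames(rep(c("A", "B"), each = 8),
                              G$individual_ids))$theta
  })
  expect_lt(abs(mean(thetas)), 3 * stats::sd(thetas) / sqrt(50))
})

test_that("FST is invariant to locus order and allele relabeling", {
  G <- toy_genotypes(seed = 9, n_ind = 12, n_loci = 20)
  popmap <- toy_popmap(G, 3)
  base <- wc_fst(G, popmap)$theta
  perm <- sample(20)
  expect_equal(wc_fst(G[, perm], popmap)$theta, base)
  flipped <- G
  flipped$calls <- 2L - G$calls
  expect_equal(wc_fst(flipped, popmap)$theta, base)
  expect_error(wc_fst(G, stats::setNames(rep("A", 12),
                                         G$individual_ids)), "two groups")
})

test_that("haplotype diversity reproduces published worked examples", {
  expect_equal(haplotype_diversity(c(7, 1), digits = 3), 0.250)
  expect_equal(haplotype_diversity(c(6, 2), digits = 3), 0.429)
  expect_equal(haplotype_diversity(c(13, 2, 1), digits = 3), 0.342)
  expect_equal(haplotype_diversity(c(8)), 0)
  expect_error(haplotype_diversity(c(1)), "two")
  expect_error(haplotype_diversity(c(1.5, 2)), "integer")
})

test_that("haplotype diversity lies in [0,1] and increases under evening", {
  # all configurations with n <= 12: a Robin Hood transfer from the most
  # to the least frequent class never decreases He
  for (n in 2:12) {
    parts <- list(c(n))
    for (k in 2:min(n, 4)) {
      cmb <- utils::combn(n - 1, k - 1)
      for (j in seq_len(ncol(cmb))) {
        cuts <- c(0, cmb[, j], n)
        parts[[length(parts) + 1]] <- diff(cuts)
      }
    }
    for (cnt in parts) {
      he <- haplotype_diversity(cnt)
      expect_gte(he, 0)
      expect_lte(he, 1)
      i <- which.max(cnt); j <- which.min(cnt)
      if (cnt[i] - cnt[j] >= 2) {
        evener <- cnt
        evener[i] <- evener[i] - 1
        evener[j] <- evener[j] + 1
        expect_gte(haplotype_diversity(evener), he)
      }
    }
  }
})

test_that("haplotype FST hits the fixed-difference and panmixia limits", {
  groups <- rep(c("A", "B", "C"), each = 10)
  expect_equal(haplotype_fst(groups, groups), 1)  # one haplotype per group
  set.seed(1)
  shared <- sample(paste0("h", 1:5), 30, replace = TRUE)
  expect_lt(abs(haplotype_fst(shared, groups)), 0.15)
})
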