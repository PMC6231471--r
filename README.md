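# divscape

Landscape genomics of population divergence: who did what — environment,
geography, or colonization history?

`divscape` is an R package for dissecting the drivers of among-population
genomic differentiation in structured species, built around the workflow
of a range-wide conifer landscape-genomics study design. From a
multi-population diploid SNP panel, per-population environments and
coordinates, and a uniparental haplotype table it computes:

* **Population genetics** — SNP filtering with explicit, reported rules;
  percent polymorphic loci and observed heterozygosity; Weir–Cockerham
  FST (per-locus variance components and the multilocus ratio of sums);
  unbiased haplotype diversity `He = n/(n-1)(1 − Σ p_i²)`.
* **Demography** — a three-population isolation-with-migration
  coalescent simulator (Rcpp), folded joint site-frequency spectra with
  hypergeometric down-sampling projection under missing data, multinomial
  composite-likelihood fitting with conditional-maximization cycles and
  common random numbers, Akaike-weight comparison of nine candidate
  models (three branching orders × three growth modes), block-bootstrap
  confidence intervals over genomic fragments, and conversion of scaled
  estimates to years/individuals including the clock-swap identity
  `t_new = t_old · (gen_new/gen_old) · (μ_old/μ_new)`.
* **Outlier scans** — a PCA/Mahalanobis scan with genomic-inflation
  correction and Storey q-values, an environmental-association scan
  against a population-covariance null (grid-integrated Bayes factors +
  whitened Spearman ρ), and the robust intersection rule (top-1% BF with
  BF > 3 and top-5% |ρ|, crossed with q ≤ 0.05).
* **Variance partitioning** — RDA/partial RDA of population allele
  frequencies on environmental PCs, forward-selected trend-surface
  geography and mitotype PCs, with the adjusted-R² fraction ledger
  (individual, joint, total explained) whose identity
  `env|geog + geog|env + joint = total` holds exactly.
* **Niche divergence** — per-axis dn/db resampling tests on
  correlation-PCA axes with permutation t tests, Schoener's D and
  Warren's I overlap of normalized suitability grids, and reciprocal
  background tests against pseudo-niche nulls.
* **Synthetic data** — a generator with known ground truth (cluster
  labels, spiked adaptive loci, demographic parameters) emulating a
  17-population, ~4,000-SNP, three-group dataset, used throughout the
  test suite for calibration and power studies.

## A worked example

```r
library(divscape)

## generate a synthetic study with known truth, spike 20 adaptive loci
cfg <- synth_config(n_loci = 2000, n_adaptive = 20, adaptive_beta = 3,
                    seed = 101)
b <- gen_im_dataset(cfg)
b <- spike_adaptive_loci(b, seed = 102)

## mitotype diversity of a population with counts (7, 1) over 8 trees
haplotype_diversity(c(7, 1), digits = 3)
#> [1] 0.25

## differentiation among the regional clusters
wc_fst(b$G, b$popmap, grouping = b$truth$cluster)$theta
#> [1] 0.05308913
haplotype_fst(b$mitotypes, b$clustermap)
#> [1] 0.9530337

## dual outlier scans and their robust intersection
scan <- pcadapt_scan(b$G, cattell_k(pca_structure(b$G)$eigenvalues[1:15]))
omega <- neutral_covariance(pop_allele_freqs(neutral_set(b$G, scan),
                                             b$popmap))
env <- env_assoc_scan(pop_allele_freqs(b$G, b$popmap), b$env, omega,
                      seed = 103)
sets <- robust_outliers(scan, env)
sets
#> outlier_set: 65 PCA-scan, 46 env-association, 23 robust (intersection)
mean(b$G$locus_ids[b$truth$adaptive] %in% sets$robust)
#> [1] 1
```

The 20 truly adaptive loci are all recovered by the robust intersection
of the two scans, with 3 false positives among the 1,980 neutral loci.
The mitotype FST (0.95 for this seed; about 0.81 averaged over seeds)
reflects the strongly clustered seed-dispersed marker against the much
weaker nuclear differentiation (0.05).

Variance partitioning on the robust outlier set then attributes their
among-population variance to environment versus geography
(`variance_partition()` prints the adjusted-R² ledger), and the
demography module fits the nine isolation-with-migration models to the
folded SFS (`project_folded_sfs()`, `fit_im()`, `compare_im_models()`).
`run_pipeline()` drives the whole chain and writes per-stage CSV/JSON
outputs with seeds and provenance.

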