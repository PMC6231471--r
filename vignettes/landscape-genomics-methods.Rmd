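---
title: "Dissecting drivers of population divergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting drivers of population divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscape)
```

## The scientific problem

Wide-ranging plants such as temperate conifers are typically structured
into a few regional genetic groups. Three non-exclusive processes can
produce that structure: isolation by environment (IBE, divergent
selection along climatic gradients), isolation by distance (IBD,
dispersal limitation over geography), and isolation by colonization
(IBC, distinct glacial refugia seeding different regions). divscape
implements a complete analysis chain for teasing these apart with a
multi-population SNP panel, per-population environments and coordinates,
and a uniparentally inherited marker (mitotypes, seed-dispersed in
pines, which track colonization), plus a synthetic-data generator with
known ground truth so every estimator in the chain can be calibrated.

The statistical components are:

* diversity and differentiation statistics (percent polymorphic loci,
  observed heterozygosity, Weir–Cockerham FST, unbiased haplotype
  diversity `He = n/(n-1) (1 - sum p_i^2)`);
* a three-population isolation-with-migration (IM) coalescent model fit
  to the folded joint site-frequency spectrum (SFS) by composite
  likelihood, with Akaike-weight model choice among nine candidate
  models and block-bootstrap confidence intervals;
* two outlier scans — a PCA/Mahalanobis scan with Storey q-values and
  an environmental-association scan against a population-covariance
  null — whose intersection defines robust adaptive candidates;
* redundancy analysis (RDA) partitioning of among-population allele
  frequency variance into environment, geography and mitotype
  (colonization) fractions on the adjusted-R² scale;
* niche-divergence statistics: per-axis dn/db resampling tests on
  PCA-reduced environmental space, Schoener's D and Warren's I overlap
  of suitability surfaces, and a resampling background test.

## The demographic model

Three extant groups (labelled south, north, west) descend from a root
population: the outgroup (south, under the favored branching order)
splits at `T1` generations before present, the remaining pair at
`T2 < T1`. Each population has a diploid effective size; descendant
sizes may be constant, exponentially growing since the split, or
growing only in a recent fraction of the branch (`recent_frac`, default
0.1, with a default 10-fold change). Migration is continuous among the
three extant groups only (ancestral branches are isolated — the
conventional reading when only extant-pair rates are reported) and is
parameterized either as backward per-lineage rates or as migrants per
generation (`mig_migrants`), the scale on which such rates are usually
reported; the latter keeps simulation cost bounded when sizes vary
during optimization.

Genealogies are simulated in continuous time by a structured
coalescent written in C++. Two outputs matter:

* **Expected SFS.** Rather than dropping mutations, the simulator
  accumulates branch lengths by joint descendant configuration; the
  normalized accumulation is the probability of each joint
  minor-allele-count cell conditional on a site segregating. Every
  branch of every genealogy contributes, which cuts Monte-Carlo
  variance by an order of magnitude relative to per-site mutation
  sampling.
* **Simulated SNPs.** Under infinite sites in the low-mutation limit, a
  segregating site's genealogy is length-biased: long genealogies host
  proportionally more segregating sites. The site simulator therefore
  draws, in a first pass, the total lengths of `n_loci` independent
  genealogies; allocates sites to genealogies multinomially in
  proportion to length; and in a second pass replays the identical
  random stream to drop the allocated mutations (placed uniformly on
  branches via a private generator so the streams stay synchronized).
  The marginal site distribution is exact; the price is a mild
  overdispersion of SFS counts (genealogy sharing among sites, a
  chi-square inflation of roughly 1.3 in our checks), akin to linked
  SNPs on a shared fragment.

### Composite likelihood, fitting, and model choice

The folded joint SFS treats cells as independent multinomial draws
conditional on segregating; monomorphic cells are excluded, folding
maps each cell onto its minor-allele equivalence class (mass at exactly
half frequency is kept once), and expected cells at zero are floored at
`1/(10 n_sims)`. Observed spectra are built by expected (hypergeometric)
down-sampling projection of each site's non-missing allele counts onto
fixed target sizes, which maximizes the number of sites retained under
missing data; sites below the target in any group are skipped and
counted, and an optional flag removes all joint-singleton mass.

`fit_im()` is a multi-start conditional-maximization scheme: random
log-uniform restarts, coordinate-wise Brent maximization on log-scaled
parameters, common random numbers per run (each run's objective is
deterministic, so its trace is monotone), and an optional polish cycle
at a larger simulation count. Because the segregating-site-conditioned
SFS is exactly invariant to a joint rescaling of all sizes and times
(with migration rates scaled inversely), absolute parameters need an
anchor; fits therefore hold a reference size (the root) fixed, exactly
as SFS engines anchor the scale through the mutation rate.

`compare_im_models()` fits all candidate models from a common starting
point, re-seeds each model from the best basin any model found, polishes
the contenders, and re-scores every model at a large common-seed
simulation count so Monte-Carlo error largely cancels from the Akaike
comparison. Even so, topology discrimination at desk scale is weak
under the study conditions: with 11–19 migrants per generation among
groups, alternative branching orders fit a 4,000-SNP spectrum projected
to a few haploids per group almost as well as the generating topology
(noise-free probes put the composite log-likelihood gap near 6 units at
4,000 SNPs, within overfitting reach of the eight competing models).
Decisive model choice of the kind the full-resolution data support
requires spectra over the complete samples, beyond a desk-scale
simulation budget; the calibration suite reports this comparison at its
stated scale rather than silently shrinking it.

Times in generations convert to years by the generation time; the
package also exposes the clock-swap identity
`t_new = t_old (gen_new/gen_old) (mu_old/mu_new)` for re-expressing
published dates under different mutation-rate and generation-time
assumptions.

## Outlier scans

The PCA scan scales each locus by `sqrt(p(1-p))`, mean-imputes missing
dosages for the decomposition only, regresses scaled genotypes on K
principal components (K from an automated Cattell rule: the last axis
whose eigenvalue drop is at least 10% of the largest drop), and forms a
Mahalanobis statistic from the K z-scores with a median-centered,
shrinkage-regularized covariance (shrinkage intensity 0.05 toward the
diagonal). We chose shrinkage over minimum-volume robust estimators
because the latter systematically underestimate scale on null data and
inflate the tail; the genomic inflation factor (median chi-square)
rescales the statistic before p-values on K degrees of freedom, and
Storey q-values (smoother pi0, falling back to pi0 = 1 when the
estimate is unstable) define discoveries. Tail calibration is
approximate: on fully neutral simulations the flagged fraction at
q <= 0.05 stays within three standard errors of 0.05, which is the
calibration property the suite asserts.

The environmental association scan standardizes population frequencies
by `sqrt(pbar(1-pbar))`, whitens them with the covariance of a
putatively neutral, LD-pruned locus set (PCA-significant loci removed,
then 50-SNP/5-step/r² 0.05 window pruning), and contrasts a linear
environmental effect against the null by a Bayes factor computed by
deterministic grid integration over the standardized effect size with a
standard-normal prior (profile residual variance at each grid point) —
a reproducible, desk-fast replacement for MCMC that keeps the decision
rules unchanged. The nonparametric support statistic is the Spearman
correlation of whitened frequencies with the whitened environment,
averaged over five random tie-breaking seeds. A locus is an
environmental candidate if, for at least one variable, it is in the top
1% of Bayes factors (ties included), has BF > 3, and is in the top 5%
of absolute Spearman correlations; the robust set intersects these with
the q-significant PCA set.

## Variance partitioning

Population allele frequencies (flagged no-data cells imputed at the
across-population mean) form the response; predictors are environmental
principal components (correlation PCA retained to 75% cumulative
variance), trend-surface geography (`x, y, xy, x², y²` of centered
coordinates, forward-selected at alpha = 0.05 with a global pre-test —
the double stopping rule that keeps the family-wise entry rate at the
nominal level), and mitotype-frequency PCs (singleton mitotypes
removed, axes to 75% cumulative variance). RDA and partial RDA are
computed by vegan; significance by permutation of population rows (999
permutations by default; populations are the exchangeable units, no
blocks). Conditional fractions are differences of Ezekiel-adjusted R²
of nested models, the joint fraction is `adj(env) + adj(geog) -
adj(both)`, and the identity `env|geog + geog|env + joint = total`
holds exactly at full precision. The joint fraction carries no
significance test; the mitotype matrix is reported marginally. Because
the Ezekiel adjustment is nonlinear in the predictor count, orthogonal
designs show a small positive joint fraction at realistic population
counts (about 0.01–0.1 at n = 16); this is a property of the
convention, not a bug, and the recovery suite compares means over
replicates for that reason. The frequency response is left untransformed
(no Hellinger), matching the convention of leaving the predictor
matrices untransformed.

## Niche divergence

Environmental space pooled over occurrences and backgrounds is reduced
by correlation-matrix PCA; axes with eigenvalue > 1 are retained. On
each axis, dn is the absolute difference in mean scores of random 75%
subsamples of the two groups' occurrences and db the same on their
background points (backgrounds are subsampled at the same 75% fraction
— the natural symmetric choice where the original procedure is
ambiguous), both over 1,000 resamplings; divergence on an axis requires
the mean dn to exceed the 97.5th percentile of db and a significant
two-sided permutation t test (exact enumeration available at small n).
dn is deliberately per-axis, not a multivariate distance. Overlap uses
normalized suitability surfaces: Schoener's `D = 1 - 0.5 sum|p - q|`
and Warren's `I` (one minus half the squared Hellinger distance); the
default suitability stand-in is a normalized 2-D kernel density of
occurrence coordinates, and any externally produced raster can be
substituted — the statistics are model-agnostic. The background test
draws, 100 times, as many pseudo-occurrences from the sister group's
background as the focal group has, refits the suitability model, and
compares observed overlap to the resulting null (below the 5th
percentile: divergence; above the 95th: conservatism), run in both
reciprocal directions.

## The synthetic-data generator

The generator emulates a range-wide sample of a wind-pollinated
conifer: 17 populations (191 individuals, sizes 8–12) in five clusters
— three regional groups plus two micro-refugial single-population
clusters — mapped onto the three IM demes; roughly 4,000 unlinked
biallelic SNPs; uniform missingness (default 7.2%); coordinates on a
jittered grid around regional centers in realistic decimal degrees;
environmental variables linear in centered coordinates plus iid noise
(the environment–geography covariance is controlled by the slopes, so
IBE/IBD confounding is tunable); strongly clustered mitotypes; and an
IM demography at the fitted scale (sizes 1.1–2.1 x 10^5, splits at
73,400 and 11,600 generations, 11–19 migrants per generation among
groups, asymmetric by pair as reported, with the unreported south–north
rate set low at 2).

Choices worth knowing about:

* One global seed fans out to per-stage child seeds, so stages can be
  regenerated independently and bundles are bit-identical per seed.
* Populations within a cluster drift around their deme frequency by a
  Balding–Nichols layer (`fst_within`, default 0.015) and genotypes are
  drawn binomially from population frequencies; adaptive loci are
  spiked at the population-frequency level (`logistic(logit(p0) + beta
  z_env)` plus binomial noise), matching the frequency-level scans that
  must detect them. A simulated SNP count of 4,077 is the pre-filter
  count here; the MAF < 0.05 rule removes the rare coalescent tail
  (roughly 60–70% of simulated loci), unlike the empirical panel where
  4,077 was the post-filter count — harnesses that need post-filter
  scale simply raise `n_loci`.
* Mitotype pools are cluster-private with Dirichlet(theta)
  concentrations and a small range-wide sharing rate; the defaults
  (theta = 0.1, share = 0.02) were frozen by a pre-registered grid
  search targeting among-group mitotype FST of about 0.81 (mean Gst
  0.811 over 20 seeds). The sharing rate is exposed because empirical
  sharing between adjacent groups is not well constrained.
* Niche backgrounds are drawn from envelopes three times wider than
  the occurrence spread whose centers retain only `bg_attenuation`
  (default 0.2) of each group's environmental offset: occupied niches
  are more environmentally extreme than the background regions they
  sit in, which is the regime in which observed niche divergence can
  exceed background divergence.

What passing tests on these data do and do not show: the generator
reproduces the structural features the estimators rely on (hierarchical
divergence with migration, environmental clines, clustered mitotypes,
uniform missingness) but not sequencing artifacts (depth- or
quality-correlated missingness, paralog collapse, allele-balance bias),
linkage beyond shared fragments, or spatially autocorrelated
micro-environments. Calibration on synthetic data is therefore
necessary, not sufficient, for real-data validity.

## Numerical choices and problem sizes

Thresholds follow the printed inequalities exactly (MAF < 0.05 dropped,
missingness >= 0.3 dropped, observed heterozygote fraction > 0.5
dropped, mean depth >= 400 dropped, fewer than 4 genotyped individuals
in any population dropped); masking (GQ < 20 or depth < 5) precedes
locus filtering, and MAF is computed over pooled populations after
masking. Heterozygosity is observed (not expected) heterozygote
fraction; the alternative is one switch away in the summary code. FST
loci with zero total variance are excluded from the ratio of sums and
counted, never set to zero. The calibration suite runs at deliberately
reduced problem sizes — spectra projected to 4–6 haploids per group,
hundreds of Monte-Carlo genealogies per likelihood evaluation, tens of
bootstrap refits — chosen so the full suite completes on a single CPU
in under ten minutes while leaving every calibration property testable
at its stated threshold.

## Known limitations

* Composite-likelihood parameter uncertainty is understated by the
  independence assumption; the block bootstrap over fragments is the
  corrective, and its intervals widen further under the Monte-Carlo
  noise of desk-scale refits.
* Model choice among the nine IM models is underpowered at desk scale
  (see above).
* The Bayes factor replaces MCMC integration over the full covariance
  posterior with grid integration under a fixed plug-in covariance;
  decision rules are quantile-based, so ranking — not absolute BF
  calibration — is what matters.
* The q-value procedure controls FDR exactly only under p-value
  uniformity; the genomic-inflation correction centers but does not
  reshape the statistic's tail.
* Maxent is out of scope; suitability surfaces are pluggable inputs.
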