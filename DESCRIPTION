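Package: divscape
Title: Landscape Genomics of Population Divergence: Demography, Outlier
    Scans, Variance Partitioning and Niche Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the drivers of among-population genomic
    differentiation in wide-ranging plant species. Implements SNP
    filtering and diversity/differentiation statistics (observed
    heterozygosity, percent polymorphic loci, Weir-Cockerham FST,
    unbiased haplotype diversity), a three-population
    isolation-with-migration coalescent simulator with folded joint
    site-frequency-spectrum projection and composite-likelihood model
    fitting with Akaike-weight model choice and block-bootstrap
    confidence intervals, dual outlier scans (principal-component
    Mahalanobis scan with Storey q-values and an environmental
    association scan against a population-covariance null), redundancy
    analysis partitioning of among-population variance into environment,
    geography and colonization fractions, and niche overlap and
    background-divergence resampling tests. A synthetic-data generator
    with known ground truth supports calibration and power studies of
    the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    permute,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
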