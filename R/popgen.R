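#' Mask low-confidence genotypes
#'
#' Sets individual genotype calls to missing when the per-genotype quality
#' or sequencing depth falls below threshold. No locus is removed. If the
#' matrix carries neither a depth nor a quality layer the input is returned
#' unchanged with a warning.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param gq_min genotypes with quality below this are masked.
#' @param dp_min genotypes with depth below this are masked.
#' @return a \code{genotype_matrix} with masked entries set to \code{NA}.
#' @export
mask_genotypes <- function(G, gq_min = 20, dp_min = 5) {
  if (is.null(G$gq) && is.null(G$depth)) {
    warning("no quality/depth layers present; genotypes left unmasked")
    return(G)
  }
  mask <- matrix(FALSE, nrow(G$calls), ncol(G$calls))
  if (!is.null(G$gq)) mask <- mask | (!is.na(G$gq) & G$gq < gq_min)
  if (!is.null(G$depth)) mask <- mask | (!is.na(G$depth) & G$depth < dp_min)
  calls <- G$calls
  calls[mask] <- NA_integer_
  genotype_matrix(calls, depth = G$depth, gq = G$gq, fragments = G$fragments)
}

#' Locus filter thresholds
#'
#' Thresholds follow strict inequality semantics: a locus is dropped when
#' pooled minor allele frequency is below \code{maf_min}, missing rate is at
#' least \code{missing_rate_max}, observed heterozygote fraction exceeds
#' \code{het_max}, mean depth is at least \code{mean_depth_max}, or it is
#' genotyped in fewer than \code{min_genotyped_per_pop} individuals in any
#' population.
#'
#' @param maf_min minimum pooled minor allele frequency.
#' @param missing_rate_max maximum tolerated missing-genotype fraction
#'   (loci at or above are dropped).
#' @param het_max maximum observed heterozygote fraction (strictly above
#'   is dropped).
#' @param mean_depth_max loci with mean depth at or above are dropped
#'   (paralog guard); ignored when no depth layer is present.
#' @param min_genotyped_per_pop minimum genotyped individuals per
#'   population.
#' @return a \code{filter_spec} list.
#' @export
filter_spec <- function(maf_min = 0.05, missing_rate_max = 0.3,
                        het_max = 0.5, mean_depth_max = 400,
                        min_genotyped_per_pop = 4) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            missing_rate_max >= 0, missing_rate_max <= 1,
            het_max >= 0, het_max <= 1,
            mean_depth_max > 0, min_genotyped_per_pop >= 0)
  structure(list(maf_min = maf_min, missing_rate_max = missing_rate_max,
                 het_max = het_max, mean_depth_max = mean_depth_max,
                 min_genotyped_per_pop = min_genotyped_per_pop),
            class = "filter_spec")
}

#' Filter loci on frequency, missingness, heterozygosity, depth and
#' per-population coverage
#'
#' Applies every rule of a \code{\link{filter_spec}} to each locus and
#' drops the failures, reporting the first failing rule per dropped locus
#' (rules tested in the order maf, missing, het, depth, min_per_pop).
#' Minor allele frequency is computed over all populations pooled, on the
#' (already masked) calls.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param spec a \code{\link{filter_spec}}.
#' @param popmap named vector mapping individual id to population.
#' @return list with elements \code{G} (surviving loci) and
#'   \code{rejected} (data frame: locus_id, rule).
#' @export
filter_loci <- function(G, spec = filter_spec(), popmap) {
  pop <- check_popmap(G, popmap)
  calls <- G$calls
  n_ind <- nrow(calls)
  nonmiss <- !is.na(calls)
  n_called <- colSums(nonmiss)
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  missing_rate <- 1 - n_called / n_ind
  het <- ifelse(n_called > 0,
                colSums(calls == 1, na.rm = TRUE) / n_called, 0)
  rule <- rep(NA_character_, ncol(calls))
  rule[is.na(rule) & (is.na(maf) | maf < spec$maf_min)] <- "maf"
  rule[is.na(rule) & missing_rate >= spec$missing_rate_max] <- "missing"
  rule[is.na(rule) & het > spec$het_max] <- "het"
  if (!is.null(G$depth)) {
    mean_depth <- colMeans(G$depth, na.rm = TRUE)
    rule[is.na(rule) & mean_depth >= spec$mean_depth_max] <- "depth"
  }
  if (spec$min_genotyped_per_pop > 0) {
    per_pop <- rowsum(nonmiss + 0L, pop)  # pops x loci counts
    under <- apply(per_pop < spec$min_genotyped_per_pop, 2, any)
    rule[is.na(rule) & under] <- "min_per_pop"
  }
  keep <- is.na(rule)
  if (!any(keep)) warning("all loci were filtered out")
  list(G = G[, keep],
       rejected = data.frame(locus_id = G$locus_ids[!keep],
                             rule = rule[!keep],
                             stringsAsFactors = FALSE))
}

#' Population allele frequencies
#'
#' Alt-allele frequency per population and locus, computed as alt alleles
#' over non-missing allele count. Cells with zero non-missing calls are
#' \code{NA} and flagged.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named vector mapping individual id to population.
#' @return a \code{pop_freqs} object: list with \code{freq} (pops x loci),
#'   \code{n} (non-missing allele counts) and \code{flagged} (logical).
#' @export
pop_allele_freqs <- function(G, popmap) {
  pop <- check_popmap(G, popmap)
  nonmiss <- !is.na(G$calls)
  calls0 <- G$calls
  calls0[!nonmiss] <- 0L
  alt <- rowsum(calls0, pop)
  n <- 2 * rowsum(nonmiss + 0L, pop)
  freq <- ifelse(n > 0, alt / n, NA_real_)
  structure(list(freq = freq, n = n, flagged = n == 0,
                 populations = rownames(alt), locus_ids = G$locus_ids),
            class = "pop_freqs")
}

#' Per-population diversity summary
#'
#' Percent polymorphic loci (share of loci where both alleles are observed
#' within the population) and mean per-locus heterozygosity: by default
#' the observed heterozygote fraction among non-missing individuals;
#' \code{type = "expected"} switches to unbiased expected heterozygosity
#' 2n/(2n-1) 2p(1-p).
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named vector mapping individual id to population.
#' @param type observed or expected heterozygosity.
#' @return data frame: population, n, pct_poly, het.
#' @export
diversity_summary <- function(G, popmap,
                              type = c("observed", "expected")) {
  type <- match.arg(type)
  pop <- check_popmap(G, popmap)
  res <- lapply(levels(pop), function(p) {
    sub <- G$calls[pop == p, , drop = FALSE]
    nonmiss <- !is.na(sub)
    n_called <- colSums(nonmiss)
    any_alt <- colSums(sub > 0, na.rm = TRUE) > 0
    any_ref <- colSums(sub < 2, na.rm = TRUE) > 0
    poly <- any_alt & any_ref & n_called > 0
    het_l <- if (type == "observed") {
      ifelse(n_called > 0,
             colSums(sub == 1, na.rm = TRUE) / n_called, NA_real_)
    } else {
      pl <- ifelse(n_called > 0,
                   colSums(sub, na.rm = TRUE) / (2 * n_called), NA_real_)
      ifelse(n_called > 0,
             2 * n_called / (2 * n_called - 1) * 2 * pl * (1 - pl),
             NA_real_)
    }
    data.frame(population = p, n = sum(pop == p),
               pct_poly = 100 * mean(poly[n_called > 0]),
               het = mean(het_l, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Weir-Cockerham FST
#'
#' Per-locus theta and the multilocus ratio-of-sums estimate from the
#' Weir & Cockerham (1984) variance components a (among populations),
#' b (among individuals within populations) and c (within individuals).
#' Loci where the total variance a+b+c is zero or undefined (fewer than two
#' populations with data) are excluded from the multilocus ratio and
#' counted.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param popmap named vector mapping individual id to population.
#' @param grouping optional named vector population -> group; when given,
#'   differentiation is estimated among groups rather than populations.
#' @return list with \code{theta} (multilocus), \code{per_locus} (data
#'   frame locus_id, a, b, c, theta) and \code{n_skipped}.
#' @export
wc_fst <- function(G, popmap, grouping = NULL) {
  pop <- check_popmap(G, popmap)
  if (!is.null(grouping)) {
    g <- as.character(grouping[as.character(pop)])
    if (anyNA(g)) stop("grouping does not cover all populations")
    pop <- factor(g)
  }
  if (nlevels(pop) < 2) stop("need at least two groups with data")
  calls <- G$calls
  nonmiss <- !is.na(calls)
  calls0 <- calls
  calls0[!nonmiss] <- 0L
  ni <- rowsum(nonmiss + 0L, pop)          # groups x loci diploid counts
  alt <- rowsum(calls0, pop)
  het <- rowsum((calls == 1) + 0L, pop, na.rm = TRUE)
  pfr <- ifelse(ni > 0, alt / (2 * ni), 0)
  hfr <- ifelse(ni > 0, het / ni, 0)

  r <- colSums(ni > 0)                     # groups with data per locus
  sum_n <- colSums(ni)
  nbar <- ifelse(r > 0, sum_n / r, NA_real_)
  sum_n2 <- colSums(ni^2)
  nc <- ifelse(r > 1, (sum_n - sum_n2 / sum_n) / (r - 1), NA_real_)
  pbar <- ifelse(sum_n > 0, colSums(ni * pfr) / sum_n, NA_real_)
  s2 <- ifelse(r > 1, colSums(ni * (sweep(pfr, 2, pbar))^2) /
                 ((r - 1) * nbar), NA_real_)
  hbar <- ifelse(sum_n > 0, colSums(ni * hfr) / sum_n, NA_real_)

  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  ok <- r >= 2 & is.finite(denom) & denom != 0 & nbar > 1
  theta_l <- ifelse(ok, a / denom, NA_real_)
  list(theta = sum(a[ok]) / sum(denom[ok]),
       per_locus = data.frame(locus_id = G$locus_ids, a = a, b = b, c = cc,
                              theta = theta_l, stringsAsFactors = FALSE),
       n_skipped = sum(!ok))
}

#' Unbiased haplotype (mitotype) diversity
#'
#' He = n/(n-1) (1 - sum p_i^2) for haplotype counts, the sample-size
#' corrected gene diversity commonly reported for uniparental markers.
#'
#' @param counts positive integer vector of haplotype counts (n = sum >= 2).
#' @param digits optional rounding of the reported value (summary tables
#'   conventionally print 3 decimals); \code{NULL} keeps full precision.
#' @return numeric He in [0, 1].
#' @export
haplotype_diversity <- function(counts, digits = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least two sampled sequences")
  p <- counts / n
  he <- n / (n - 1) * (1 - sum(p^2))
  if (!is.null(digits)) he <- round(he, digits)
  he
}

#' Among-group haplotype differentiation (Gst)
#'
#' Nei's Gst on categorical haplotype labels: (Ht - Hs)/Ht with unbiased
#' gene diversities, where Hs is the sample-size weighted mean within-group
#' diversity and Ht the pooled diversity.
#'
#' @param haplotypes character vector of haplotype labels per individual.
#' @param groups parallel vector of group labels.
#' @return numeric Gst (0 for panmixia, 1 for fixed differences).
#' @export
haplotype_fst <- function(haplotypes, groups) {
  stopifnot(length(haplotypes) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  he <- function(x) {
    n <- length(x)
    if (n < 2) return(0)
    p <- table(x) / n
    n / (n - 1) * (1 - sum(p^2))
  }
  ns <- tabulate(groups)
  hs <- sum(ns * vapply(levels(groups), function(g)
    he(haplotypes[groups == g]), numeric(1))) / sum(ns)
  ht <- he(haplotypes)
  if (ht == 0) return(0)
  (ht - hs) / ht
}
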