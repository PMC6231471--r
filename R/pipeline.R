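#' Run the full analysis chain on a synthetic dataset
#'
#' Orchestrates the end-to-end workflow: data generation (with adaptive
#' spiking), genotype filtering, diversity and differentiation summaries,
#' folded-SFS demographic fitting, the two outlier scans with their
#' robust intersection, RDA variance partitioning on neutral and outlier
#' SNP sets, and the niche-divergence tests. Every stage writes CSV/JSON
#' outputs plus a provenance record (seed, parameters) when \code{out_dir}
#' is given; stage results are also returned. All randomness derives from
#' the single seed, so reruns are reproducible.
#'
#' @param config a \code{\link{synth_config}} (its seed is overridden by
#'   \code{seed} when supplied).
#' @param out_dir optional output directory.
#' @param seed global seed.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("synth", "filter", "stats", "demography", "outliers",
#'   "partition", "niche")}; later stages require earlier ones.
#' @param fit_settings list of demographic-fit settings (models to
#'   compare, runs, cycles, n_sims, projection sizes).
#' @return named list of stage results.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         seed = config$seed,
                         stages = c("synth", "filter", "stats",
                                    "demography", "outliers", "partition",
                                    "niche"),
                         fit_settings = list()) {
  config$seed <- seed
  fs <- utils::modifyList(
    list(models = list(best = model_spec("south_first", "constant")),
         project = c(8, 8, 8), n_runs = 2, cycles = 2, n_sims = 300),
    fit_settings)
  seeds <- child_seeds(seed + 1, 8)
  res <- list(seed = seed)
  emit <- function(stage, obj, files = list()) {
    if (is.null(out_dir)) return(invisible())
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(files))
      utils::write.csv(files[[nm]],
                       file.path(out_dir, paste0(stage, "_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(stage = stage, seed = seed, time = as.character(Sys.time())),
      file.path(out_dir, paste0(stage, "_provenance.json")),
      auto_unbox = TRUE)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(NULL)
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # synth
  bundle <- run_stage("synth", function() {
    b <- gen_im_dataset(config)
    if (config$n_adaptive > 0)
      b <- spike_adaptive_loci(b, seed = seeds[1])
    if (!is.null(out_dir)) write_bundle(b, file.path(out_dir, "data"))
    emit("synth", b)
    b
  })
  res$bundle <- bundle
  if (is.null(bundle)) return(res)

  # filter
  filt <- run_stage("filter", function() {
    f <- filter_loci(bundle$G, filter_spec(), bundle$popmap)
    emit("filter", f, list(rejected = f$rejected))
    f
  })
  res$filter <- filt
  G <- if (is.null(filt)) bundle$G else filt$G

  # stats (Table-1-style report)
  res$stats <- run_stage("stats", function() {
    div <- diversity_summary(G, bundle$popmap)
    mito_he <- vapply(rownames(bundle$coords), function(p) {
      cnt <- table(bundle$mitotypes[bundle$popmap == p])
      if (sum(cnt) < 2) NA_real_ else haplotype_diversity(cnt, digits = 3)
    }, numeric(1))
    div$mito_he <- mito_he[div$population]
    fst <- wc_fst(G, bundle$popmap, grouping = bundle$truth$cluster)
    mfst <- haplotype_fst(bundle$mitotypes,
                          bundle$clustermap[names(bundle$mitotypes)])
    emit("stats", NULL, list(diversity = div))
    list(diversity = div, fst_groups = fst$theta, mito_fst = mfst)
  })

  # demography
  res$demography <- run_stage("demography", function() {
    demes <- bundle$truth$deme_of_pop[bundle$popmap]
    obs <- project_folded_sfs(bundle$G, stats::setNames(
      demes, names(bundle$popmap)),
      stats::setNames(fs$project, c("south", "north", "west")))
    fits <- lapply(fs$models, function(m)
      fit_im(obs, m, n_runs = fs$n_runs, cycles = fs$cycles,
             n_sims = fs$n_sims, seed = seeds[2]))
    cmp <- if (length(fits) >= 2) akaike_weights(fits) else NULL
    if (!is.null(out_dir)) {
      write_sfs(obs, file.path(out_dir, "demography_sfs.txt"))
      jsonlite::write_json(
        lapply(fits, function(f) list(
          loglik = f$loglik, AIC = f$AIC,
          branching = f$model$branching_order,
          growth = f$model$growth_mode)),
        file.path(out_dir, "demography_fits.json"), auto_unbox = TRUE,
        digits = NA)
    }
    emit("demography", NULL,
         if (is.null(cmp)) list() else list(model_comparison = cmp))
    list(sfs = obs, fits = fits, comparison = cmp)
  })

  # outlier scans
  res$outliers <- run_stage("outliers", function() {
    pca <- pca_structure(G)
    K <- cattell_k(pca$eigenvalues[1:min(20, length(pca$eigenvalues))])
    scan <- pcadapt_scan(G, K)
    neutral <- neutral_set(G, scan)
    omega <- neutral_covariance(pop_allele_freqs(neutral, bundle$popmap))
    freqs <- pop_allele_freqs(G, bundle$popmap)
    env <- env_assoc_scan(freqs, bundle$env, omega, seed = seeds[3])
    sets <- robust_outliers(scan, env)
    emit("outliers", NULL, list(
      per_snp = data.frame(locus_id = scan$locus_id, stat = scan$stat,
                           p = scan$p, q = scan$q,
                           bf_max = apply(env$bf, 1, max),
                           rho_max = apply(abs(env$rho), 1, max)),
      attribution = sets$attribution))
    list(K = K, scan = scan, env = env, sets = sets,
         neutral_loci = neutral$locus_ids)
  })

  # partition
  res$partition <- run_stage("partition", function() {
    if (is.null(res$outliers)) stop("requires the outliers stage")
    env_pcs <- pca_reduce(bundle$env, criterion = "cum_var",
                          cum_var = 0.75)$scores
    ts <- trend_surface(bundle$coords)
    sel <- forward_select(pop_allele_freqs(G, bundle$popmap), ts,
                          n_perm = 199, seed = seeds[4])
    geog <- if (length(sel)) ts[, sel, drop = FALSE]
            else ts[, "y", drop = FALSE]
    mito <- mito_constraints(bundle$mitotypes, bundle$popmap)$scores
    part_of <- function(loci) {
      sub <- G[, G$locus_ids %in% loci]
      variance_partition(pop_allele_freqs(sub, bundle$popmap),
                         env_pcs, geog, mito, n_perm = 199,
                         seed = seeds[5])
    }
    sets <- res$outliers$sets
    out <- list(
      neutral = part_of(setdiff(G$locus_ids,
                                union(sets$pca_set, sets$env_set))))
    if (length(sets$robust) > 1) out$robust <- part_of(sets$robust)
    emit("partition", NULL,
         list(neutral = out$neutral$table,
              robust = if (!is.null(out$robust)) out$robust$table
                       else data.frame()))
    out
  })

  # niche
  res$niche <- run_stage("niche", function() {
    cl <- bundle$truth$cluster
    major <- names(which(table(cl) >= 2))
    centers <- do.call(rbind, lapply(major, function(g)
      colMeans(bundle$env[names(cl)[cl == g], , drop = FALSE])))
    rownames(centers) <- major
    np <- gen_niche_points(centers, spread = 1, n_occ = 40, n_bg = 400,
                           seed = seeds[6])
    axes <- niche_axes(np$samples)
    pairs <- utils::combn(major, 2, simplify = FALSE)
    div <- lapply(pairs, function(pr)
      dn_db_test(np$samples[[pr[1]]], np$samples[[pr[2]]], axes,
                 n_resample = 200, n_perm = 199, seed = seeds[7]))
    names(div) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    overlap <- lapply(pairs, function(pr)
      c(D = schoener_d(np$grids[[pr[1]]], np$grids[[pr[2]]]),
        I = warren_i(np$grids[[pr[1]]], np$grids[[pr[2]]])))
    names(overlap) <- names(div)
    emit("niche", NULL, list(divergence = do.call(rbind, div)))
    list(axes = axes, divergence = div, overlap = overlap)
  })

  res
}
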