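#' Read a VCF into a genotype matrix
#'
#' Parses a VCFv4.2 file (via vcfR), keeping biallelic SNPs only
#' (multiallelic records are skipped and counted), extracting GT as
#' alt-allele dosage with \code{./.} as missing, and DP/GQ FORMAT fields
#' as layers when present.
#'
#' @param path VCF file path.
#' @return a \code{\link{genotype_matrix}}; attribute
#'   \code{n_multiallelic_skipped} reports skipped records.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  ref <- vcfR::getREF(v)
  bi <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 & alt != "."
  n_skip <- sum(!bi)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  ids <- vcfR::getID(v)
  if (all(is.na(ids)))
    ids <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  layer <- function(el) {
    if (!el %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) return(NULL)
    m <- suppressWarnings(
      vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    t(m)
  }
  G <- genotype_matrix(t(dose), individual_ids = colnames(gt),
                       locus_ids = ids, depth = layer("DP"),
                       gq = layer("GQ"))
  attr(G, "n_multiallelic_skipped") <- n_skip
  G
}

#' Write a genotype matrix as minimal VCFv4.2
#'
#' GT-only records (plus DP/GQ when layers are present) on a synthetic
#' single-"chromosome" coordinate system; coordinates are opaque
#' identifiers.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=divscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  has_dp <- !is.null(G$depth)
  has_gq <- !is.null(G$gq)
  if (has_dp) writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">', con)
  if (has_gq) writeLines('##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", G$individual_ids),
                   collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"),
               collapse = ":")
  for (l in seq_len(ncol(G$calls))) {
    g <- G$calls[, l]
    cells <- ifelse(is.na(g), "./.", gt_code[g + 1])
    if (has_dp)
      cells <- paste(cells, ifelse(is.na(G$depth[, l]), ".",
                                   G$depth[, l]), sep = ":")
    if (has_gq)
      cells <- paste(cells, ifelse(is.na(G$gq[, l]), ".",
                                   G$gq[, l]), sep = ":")
    writeLines(paste(c("1", l, G$locus_ids[l], "A", "G", ".", "PASS",
                       ".", fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic bundle to plain-text files
#'
#' Genotypes as minimal VCF, popmap/coords/env/mitotypes as headered CSV,
#' the truth record as JSON and the configuration as a key:value text
#' file.
#'
#' @param bundle a \code{synth_bundle}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$G, file.path(dir, "genotypes.vcf"))
  utils::write.csv(data.frame(individual = names(bundle$popmap),
                              population = unname(bundle$popmap)),
                   file.path(dir, "popmap.csv"), row.names = FALSE)
  utils::write.csv(data.frame(population = rownames(bundle$coords),
                              bundle$coords),
                   file.path(dir, "coords.csv"), row.names = FALSE)
  utils::write.csv(data.frame(population = rownames(bundle$env),
                              bundle$env),
                   file.path(dir, "env.csv"), row.names = FALSE)
  utils::write.csv(data.frame(individual = names(bundle$mitotypes),
                              mitotype = unname(bundle$mitotypes)),
                   file.path(dir, "mitotypes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(adaptive = bundle$truth$adaptive, beta = bundle$truth$beta,
         cluster = as.list(bundle$truth$cluster)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- bundle$config
  keys <- c("n_loci", "missing_rate", "fst_within", "n_adaptive",
            "adaptive_beta", "mito_theta", "mito_share", "seed")
  writeLines(paste0(keys, ": ", vapply(cfg[keys], format, character(1))),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Serialize a folded SFS as plain text
#'
#' A header line with the haploid dimensions followed by the flattened
#' entry vector (column-major), in the spirit of multidimensional
#' observed-SFS layouts.
#'
#' @param sfs a \code{\link{folded_sfs}}.
#' @param path output file.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("dims:", sfs$dims), collapse = " "), con)
  writeLines(paste(as.vector(sfs$entries), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[1], " +")[[1]][-1])
  entries <- array(as.numeric(strsplit(lines[2], " +")[[1]]), dims + 1L)
  folded_sfs(entries, dims)
}
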