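#' Diploid genotype matrix
#'
#' Container for multi-population diploid SNP genotypes: an individuals x
#' loci matrix of alt-allele dosages (0, 1, 2) with \code{NA} marking
#' missing calls, plus optional per-genotype depth and quality layers and
#' per-locus fragment labels (used as resampling blocks by the block
#' bootstrap).
#'
#' @param calls integer matrix, individuals x loci; entries in
#'   \code{c(0, 1, 2, NA)}.
#' @param individual_ids,locus_ids unique character identifiers; defaults
#'   derived from dimnames or generated.
#' @param depth,gq optional numeric matrices of the same shape as
#'   \code{calls} (per-genotype sequencing depth and genotype quality).
#' @param fragments optional per-locus labels tagging loci that share a
#'   sequenced fragment (linkage blocks).
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, individual_ids = NULL, locus_ids = NULL,
                            depth = NULL, gq = NULL, fragments = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (is.null(individual_ids))
    individual_ids <- rownames(calls) %||% paste0("ind", seq_len(nrow(calls)))
  if (is.null(locus_ids))
    locus_ids <- colnames(calls) %||% paste0("locus", seq_len(ncol(calls)))
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  stopifnot(length(individual_ids) == nrow(calls),
            length(locus_ids) == ncol(calls))
  dimnames(calls) <- list(individual_ids, locus_ids)
  for (layer in list(depth, gq))
    if (!is.null(layer) && !all(dim(layer) == dim(calls)))
      stop("depth/gq layers must match the call matrix dimensions")
  if (!is.null(fragments) && length(fragments) != ncol(calls))
    stop("fragments must give one label per locus")
  structure(list(calls = calls, individual_ids = individual_ids,
                 locus_ids = locus_ids, depth = depth, gq = gq,
                 fragments = fragments),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * nm / length(x$calls)))
  if (!is.null(x$depth)) cat("  with per-genotype depth layer\n")
  if (!is.null(x$gq)) cat("  with per-genotype quality layer\n")
  if (!is.null(x$fragments))
    cat(sprintf("  %d fragments\n", length(unique(x$fragments))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a \code{genotype_matrix}.
#' @param i,j individual and locus indices (any standard matrix index).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  calls <- x$calls[i, j, drop = FALSE]
  # resampling with replacement duplicates loci; keep ids unique
  colnames(calls) <- make.unique(colnames(calls))
  genotype_matrix(calls,
                  depth = sub(x$depth), gq = sub(x$gq),
                  fragments = if (is.null(x$fragments)) NULL else {
                    names(x$fragments) <- NULL
                    x$fragments[j]
                  })
}

check_popmap <- function(G, popmap) {
  if (is.null(names(popmap)))
    stop("popmap must be a named vector (individual -> population)")
  miss <- setdiff(G$individual_ids, names(popmap))
  if (length(miss))
    stop("popmap does not cover individuals: ", paste(miss, collapse = ", "))
  factor(as.character(popmap[G$individual_ids]))
}
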