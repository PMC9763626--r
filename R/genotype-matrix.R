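#' Construct a genotype matrix object
#'
#' A light container coupling an accessions x SNPs dosage matrix (counts of
#' the alternate allele, 0/1/2, `NA` = missing call) with its variant table.
#'
#' @param dosages integer matrix, accessions in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` and optionally `id`; one row per SNP column. Positions must
#'   be strictly increasing within each chromosome.
#' @param sample_ids character vector of accession identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("ACC", seq_len(nrow(dosages)))
  stopifnot(is.data.frame(variants), nrow(variants) == ncol(dosages),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            length(sample_ids) == nrow(dosages))
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop_named("invalid_dosage", "dosages must be 0, 1, 2 or NA")
  if (is.null(variants$id))
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop_named("unsorted_positions",
                 "positions must be strictly increasing within chromosome %s", ch)
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNP index
#'
#' @param G a `genotype_matrix`.
#' @param snps integer or logical index over SNP columns.
#' @param samples optional index over accessions.
#' @return A `genotype_matrix` restricted to the selected SNPs/samples.
#' @export
subset_snps <- function(G, snps, samples = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages[, snps, drop = FALSE]
  v <- G$variants[snps, , drop = FALSE]
  ids <- G$sample_ids
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  rownames(v) <- NULL
  genotype_matrix(d, v, ids)
}

# allele frequency of the alternate allele, per SNP, from non-missing calls
alt_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

# minor allele frequency per SNP
snp_maf <- function(G) {
  p <- alt_freq(G)
  pmin(p, 1 - p)
}

# per-SNP missing call fraction
snp_missing <- function(G) {
  colMeans(is.na(G$dosages))
}

# mean-impute missing dosages per SNP, returning a plain numeric matrix
impute_dosages <- function(G) {
  X <- G$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  storage.mode(X) <- "double"
  X
}
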