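#' Cluster significant SNPs into association loci
#'
#' Single-linkage chaining of significant SNPs: consecutive significant
#' SNPs on one chromosome join the same locus when their gap is smaller
#' than `merge_bp`; chained loci spanning more than `max_span_bp` are
#' abandoned (their SNPs are discarded with them), and loci with fewer than
#' `min_snps` member SNPs are discarded as likely false-positive clusters.
#' The lead SNP is the member with the lowest P-value (ties broken by
#' smallest position). Locus boundaries are the min/max positions of the
#' member SNPs.
#'
#' @param records an `assoc_result` (or data.frame with chrom, pos, p and
#'   optionally snp), already restricted to significant SNPs, or a full scan
#'   plus a `threshold` to filter on.
#' @param threshold optional P-value threshold applied to `records$p`.
#' @param merge_bp maximum gap joining adjacent significant SNPs (default
#'   1 Mb).
#' @param max_span_bp maximum locus span before it is abandoned (default
#'   30 Mb).
#' @param min_snps minimum member SNPs ("more than five" read as >= 6).
#' @param trait optional trait label stored with each locus.
#' @return data.frame of class `locus_set`: trait, chrom, start, end,
#'   n_snps, lead_snp, lead_pos, lead_p.
#' @export
cluster_loci <- function(records, threshold = NULL, merge_bp = 1e6,
                         max_span_bp = 3e7, min_snps = 6, trait = NA_character_) {
  stopifnot(is.data.frame(records), all(c("chrom", "pos", "p") %in% names(records)))
  if (!is.null(threshold)) records <- records[records$p <= threshold, , drop = FALSE]
  empty <- data.frame(trait = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_snps = integer(),
                      lead_snp = character(), lead_pos = numeric(),
                      lead_p = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("locus_set", "data.frame")
  if (nrow(records) == 0) return(empty)
  if (is.null(records$snp))
    records$snp <- paste0(records$chrom, ":", records$pos)
  records <- unique(records[, c("snp", "chrom", "pos", "p")])
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(records$chrom)) {
    r <- records[records$chrom == ch, , drop = FALSE]
    gap_new <- c(TRUE, diff(r$pos) >= merge_bp)
    grp <- cumsum(gap_new)
    for (g in unique(grp)) {
      sub <- r[grp == g, , drop = FALSE]
      span <- max(sub$pos) - min(sub$pos)
      if (span > max_span_bp) next           # abandoned, SNPs discarded
      if (nrow(sub) < min_snps) next
      lead <- sub[order(sub$p, sub$pos), ][1, ]
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, chrom = ch,
        start = min(sub$pos), end = max(sub$pos),
        n_snps = nrow(sub),
        lead_snp = lead$snp, lead_pos = lead$pos, lead_p = lead$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("locus_set", "data.frame")
  res
}

#' Lead-SNP density per genomic window
#'
#' Counts locus lead SNPs in tiling windows per chromosome, the hotspot
#' summary used to compare trait-locus density across conditions.
#'
#' @param loci a `locus_set` (possibly concatenated over many traits).
#' @param window_bp tiling window length (default 5 Mb).
#' @param chrom_lengths optional named vector of chromosome lengths; by
#'   default windows extend to the last lead SNP per chromosome.
#' @return data.frame: chrom, start0, end, n_leads.
#' @export
hotspot_density <- function(loci, window_bp = 5e6, chrom_lengths = NULL) {
  window_bp <- check_count(window_bp, "window_bp")
  if (nrow(loci) == 0) {
    if (is.null(chrom_lengths))
      return(data.frame(chrom = character(), start0 = numeric(),
                        end = numeric(), n_leads = integer()))
    chroms <- names(chrom_lengths)
  } else {
    chroms <- unique(c(loci$chrom, names(chrom_lengths)))
  }
  out <- list()
  for (ch in chroms) {
    pos <- loci$lead_pos[loci$chrom == ch]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else if (length(pos)) max(pos) else window_bp
    nwin <- as.integer(ceiling(len / window_bp))
    cnt <- tabulate(pmin((pos - 1) %/% window_bp + 1L, nwin), nbins = nwin)
    out[[ch]] <- data.frame(chrom = ch,
                            start0 = (seq_len(nwin) - 1) * window_bp,
                            end = seq_len(nwin) * window_bp,
                            n_leads = cnt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate lead-SNP density with SNP and gene density
#'
#' Pearson correlations between window-wise lead-SNP counts and marker /
#' gene densities over the same windows. Constant vectors yield `NA`.
#'
#' @param lead_counts,snp_counts numeric vectors over aligned windows.
#' @param gene_counts optional third vector.
#' @return list with `r_lead_snp`, `p_lead_snp` and, when `gene_counts` is
#'   given, `r_lead_gene`, `p_lead_gene`.
#' @export
density_correlation <- function(lead_counts, snp_counts, gene_counts = NULL) {
  stopifnot(length(lead_counts) == length(snp_counts))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(a, b, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  cs <- safe_cor(lead_counts, snp_counts)
  out <- list(r_lead_snp = cs$r, p_lead_snp = cs$p)
  if (!is.null(gene_counts)) {
    stopifnot(length(gene_counts) == length(lead_counts))
    cg <- safe_cor(lead_counts, gene_counts)
    out$r_lead_gene <- cg$r
    out$p_lead_gene <- cg$p
  }
  out
}

#' Colocalize two locus sets by interval overlap
#'
#' Reports every pair of loci (one from each set) on the same chromosome
#' whose [start, end] intervals intersect — e.g. metabolite loci against
#' drought-sensitivity loci.
#'
#' @param loci_a,loci_b `locus_set` data.frames.
#' @return data.frame with one row per overlapping pair: trait/coordinates
#'   from both sides.
#' @export
colocalize <- function(loci_a, loci_b) {
  out <- list()
  if (nrow(loci_a) && nrow(loci_b)) {
    for (i in seq_len(nrow(loci_a))) {
      a <- loci_a[i, ]
      hit <- loci_b$chrom == a$chrom &
        loci_b$start <= a$end & loci_b$end >= a$start
      for (j in which(hit)) {
        b <- loci_b[j, ]
        out[[length(out) + 1L]] <- data.frame(
          trait_a = a$trait, chrom = a$chrom, start_a = a$start, end_a = a$end,
          trait_b = b$trait, start_b = b$start, end_b = b$end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(trait_a = character(), chrom = character(),
                      start_a = numeric(), end_a = numeric(),
                      trait_b = character(), start_b = numeric(),
                      end_b = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
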