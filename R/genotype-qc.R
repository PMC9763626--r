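#' Filter variants by minor allele frequency and missingness
#'
#' Keeps SNPs with MAF >= `maf_min` (computed on non-missing alleles) and
#' missing call fraction <= `mcf_max`, preserving SNP order. An empty result
#' is permitted with a warning.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param mcf_max maximum missing call fraction (default 0.1).
#' @return The filtered `genotype_matrix`.
#' @export
filter_variants <- function(G, maf_min = 0.05, mcf_max = 0.1) {
  stopifnot(inherits(G, "genotype_matrix"))
  check_fraction(maf_min, "maf_min", 0, 0.5)
  check_fraction(mcf_max, "mcf_max")
  keep <- snp_maf(G) >= maf_min & snp_missing(G) <= mcf_max
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no SNPs survive the MAF/missingness filter")
  out <- subset_snps(G, keep)
  attr(out, "subpop") <- attr(G, "subpop")
  out
}

#' Prune SNPs in local linkage disequilibrium
#'
#' Sliding-window pairwise pruning: within windows of `window` SNPs
#' advancing by `step` (never spanning chromosomes), any pair of retained
#' SNPs with squared Pearson dosage correlation > `r2_max`
#' (pairwise-complete observations) loses its lower-MAF member (ties drop
#' the SNP at the later position); this repeats until no pair in any window
#' exceeds the threshold. Defaults mirror the common `50 5 0.2` setting.
#'
#' @param G a filtered [genotype_matrix()].
#' @param window window size in SNPs.
#' @param step window step in SNPs.
#' @param r2_max r-squared threshold above which one SNP of a pair is
#'   removed.
#' @return Integer vector of retained SNP column indices (relative to `G`).
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(G, "genotype_matrix"))
  window <- check_count(window, "window", 2L)
  step <- check_count(step, "step", 1L)
  check_fraction(r2_max, "r2_max")
  maf <- snp_maf(G)
  X <- G$dosages
  storage.mode(X) <- "double"
  keep <- rep(TRUE, ncol(X))
  chroms <- G$variants$chrom
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    mc <- length(idx)
    starts <- seq(1L, max(1L, mc), by = step)
    repeat {
      removed_any <- FALSE
      for (s in starts) {
        w <- idx[s:min(s + window - 1L, mc)]
        w <- w[keep[w]]
        if (length(w) < 2) next
        cc <- suppressWarnings(stats::cor(X[, w, drop = FALSE],
                                          use = "pairwise.complete.obs"))
        r2 <- cc^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (TRUE) {
          mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[mx[1], mx[2]] <= r2_max) break
          a <- w[mx[1]]; b <- w[mx[2]]
          # drop the lower-MAF member; tie -> the later position
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)
          keep[drop] <- FALSE
          removed_any <- TRUE
          di <- which(w == drop)
          r2[di, ] <- 0
          r2[, di] <- 0
        }
      }
      if (!removed_any) break
    }
  }
  which(keep)
}

#' Centered realised kinship matrix
#'
#' K = Xc Xc' / m, where Xc is the per-SNP mean-centered dosage matrix
#' (missing calls mean-imputed per SNP) over the m SNPs in `G`. Symmetric
#' and positive semi-definite by construction.
#'
#' @param G a filtered [genotype_matrix()].
#' @param exclude_chrom optional chromosome(s) to leave out
#'   (leave-one-chromosome-out kinship, the standard way to avoid proximal
#'   contamination when testing SNPs on that chromosome).
#' @return An accessions x accessions numeric matrix with attribute
#'   `method = "centered"`.
#' @export
kinship <- function(G, exclude_chrom = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.null(exclude_chrom))
    G <- subset_snps(G, !(G$variants$chrom %in% exclude_chrom))
  m <- ncol(G$dosages)
  if (m == 0) stop_named("invalid_argument", "no SNPs to compute kinship from")
  X <- impute_dosages(G)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / m
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  attr(K, "method") <- "centered"
  K
}

#' Principal-component structure covariates
#'
#' Top principal-component scores of the standardized (per-SNP centered and
#' unit-variance scaled), mean-imputed dosage matrix; the usual linear-
#' mixed-model proxy for population structure when model-based ancestry
#' fractions are not computed. Score columns are centered at zero and
#' mutually orthogonal.
#'
#' @param G a filtered (ideally LD-pruned) [genotype_matrix()].
#' @param n_components number of components (default 6).
#' @return accessions x `n_components` score matrix with attribute
#'   `var_explained`.
#' @export
structure_covariates <- function(G, n_components = 6) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_components <- check_count(n_components, "n_components")
  n <- nrow(G$dosages)
  if (n_components >= n)
    stop_named("invalid_argument", "n_components must be < number of accessions")
  X <- impute_dosages(G)
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- G$sample_ids
  attr(scores, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity uses the unbiased estimator
#' pi_site = 2 p (1 - p) * 2N / (2N - 1), with p the alternate allele
#' frequency and N the number of non-missing diploid calls at the site.
#' Windows of `window_bp` tile each chromosome from position 1 (half-open,
#' 1-based internally; reported with 0-based starts, BED-like), and the
#' window value is the sum of site diversities divided by the window
#' length in bp.
#'
#' @param G a [genotype_matrix()].
#' @param window_bp window length in bp (default 1 Mb).
#' @return data.frame: chrom, start0, end, n_sites, pi.
#' @export
windowed_pi <- function(G, window_bp = 1e6) {
  stopifnot(inherits(G, "genotype_matrix"))
  window_bp <- check_count(window_bp, "window_bp")
  X <- G$dosages
  N <- colSums(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  site_pi <- ifelse(N > 0 & 2 * N > 1,
                    2 * p * (1 - p) * (2 * N) / (2 * N - 1), 0)
  out <- list()
  for (ch in unique(G$variants$chrom)) {
    idx <- which(G$variants$chrom == ch)
    pos <- G$variants$pos[idx]
    win <- (pos - 1L) %/% window_bp          # 0-based window index
    nwin <- max(win) + 1L
    acc <- numeric(nwin); cnt <- integer(nwin)
    for (k in seq_along(idx)) {
      w <- win[k] + 1L
      acc[w] <- acc[w] + site_pi[idx[k]]
      cnt[w] <- cnt[w] + 1L
    }
    out[[ch]] <- data.frame(
      chrom = ch,
      start0 = (seq_len(nwin) - 1L) * window_bp,
      end = seq_len(nwin) * window_bp,
      n_sites = cnt,
      pi = acc / window_bp,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
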