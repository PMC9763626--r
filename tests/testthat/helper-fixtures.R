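# Shared fixtures and independent reference implementations (oracles).

# small genotype matrix built by hand
toy_genotypes <- function(dosages, pos = NULL, chrom = NULL) {
  m <- ncol(dosages)
  genotype_matrix(
    dosages,
    data.frame(chrom = chrom %||% rep("chr1H", m),
               pos = pos %||% (seq_len(m) * 1000L),
               ref = rep("A", m), alt = rep("T", m),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

no_qtl <- data.frame(snp = integer(), metabolite = integer(), pve = numeric())

small_cfg <- function(...) {
  args <- list(n_accessions = 60, n_snps = 140, n_metabolites = 10,
               n_inducible = 0, n_constitutive = 0, planted_qtls = no_qtl,
               seed = 1)
  extra <- list(...)
  for (nm in names(extra)) args[[nm]] <- extra[[nm]]
  do.call(sim_config, args)
}

# exhaustive reference implementation of the locus chaining rules:
# walk sorted significant SNPs, chain while gap < merge_bp, then apply the
# span and member-count filters and pick the lead by (p, pos)
oracle_cluster <- function(df, merge_bp = 1e6, max_span_bp = 3e7, min_snps = 6) {
  df <- unique(df[, c("chrom", "pos", "p")])
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  loci <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    i <- 1
    while (i <= nrow(d)) {
      j <- i
      while (j < nrow(d) && (d$pos[j + 1] - d$pos[j]) < merge_bp) j <- j + 1
      members <- d[i:j, , drop = FALSE]
      if ((max(members$pos) - min(members$pos)) <= max_span_bp &&
          nrow(members) >= min_snps) {
        best <- members[order(members$p, members$pos), ][1, ]
        loci[[length(loci) + 1]] <- data.frame(
          chrom = ch, start = min(members$pos), end = max(members$pos),
          n_snps = nrow(members), lead_pos = best$pos, lead_p = best$p)
      }
      i <- j + 1
    }
  }
  if (!length(loci)) return(NULL)
  do.call(rbind, loci)
}

# naive repeat-until-stable LD pruning reference: same rule as ld_prune but
# recomputing correlations from scratch after every removal
oracle_prune <- function(G, window = 50, step = 5, r2_max = 0.2) {
  maf <- colMeans(G$dosages, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  X <- G$dosages; storage.mode(X) <- "double"
  keep <- rep(TRUE, ncol(X))
  repeat {
    changed <- FALSE
    for (ch in unique(G$variants$chrom)) {
      idx <- which(G$variants$chrom == ch)
      for (s in seq(1, length(idx), by = step)) {
        w <- idx[s:min(s + window - 1, length(idx))]
        repeat {
          wk <- w[keep[w]]
          if (length(wk) < 2) break
          cc <- suppressWarnings(
            stats::cor(X[, wk, drop = FALSE], use = "pairwise.complete.obs"))^2
          diag(cc) <- 0; cc[is.na(cc)] <- 0
          if (max(cc) <= r2_max) break
          mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
          a <- wk[mx[1]]; b <- wk[mx[2]]
          drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
          keep[drop] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  which(keep)
}
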