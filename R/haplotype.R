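# Haplotype classes, one-way ANOVA with Fisher LSD, and allele composition
# of phenotype groups.

geno_code <- function(d) {
  c("R", "H", "A")[d + 1L]   # hom-ref, het, hom-alt
}

#' Build multi-SNP haplotype classes from genotype codes
#'
#' Concatenates per-SNP genotype states (R = hom-ref, H = het, A = hom-alt)
#' into a class string per accession. Accessions missing any constituent
#' SNP are labeled excluded and do not enter the frequency table. Classes
#' are ranked by frequency.
#'
#' @param G a [genotype_matrix()].
#' @param snp_ids variant ids (or column indices) of the constituent SNPs.
#' @return list with `table` (accession, haplotype, excluded) and `freq`
#'   (haplotype, n, freq over non-excluded accessions).
#' @export
build_haplotypes <- function(G, snp_ids) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(snp_ids) == 0) stop_named("invalid_argument", "snp_ids is empty")
  idx <- if (is.numeric(snp_ids)) as.integer(snp_ids)
         else match(snp_ids, G$variants$id)
  if (anyNA(idx) || any(idx < 1 | idx > ncol(G$dosages)))
    stop_named("invalid_argument", "snp_ids not present in G")
  D <- G$dosages[, idx, drop = FALSE]
  excluded <- apply(D, 1, anyNA)
  hap <- apply(D, 1, function(d)
    paste(ifelse(is.na(d), ".", geno_code(d)), collapse = ""))
  tab <- data.frame(accession = G$sample_ids, haplotype = hap,
                    excluded = excluded, stringsAsFactors = FALSE)
  counts <- sort(table(hap[!excluded]), decreasing = TRUE)
  freq <- data.frame(haplotype = names(counts),
                     n = as.integer(counts),
                     freq = as.numeric(counts) / sum(counts),
                     stringsAsFactors = FALSE)
  rownames(tab) <- rownames(freq) <- NULL
  list(table = tab, freq = freq)
}

#' One-way ANOVA with Fisher's protected LSD and compact letters
#'
#' Omnibus one-way ANOVA followed by pairwise least-significant-difference
#' t-tests that share the pooled within-group mean square and its degrees
#' of freedom (no multiplicity correction, per the procedure's definition;
#' protection comes from the omnibus F). Compact letters are assigned by
#' insert-and-absorb so that two classes share no letter exactly when their
#' LSD P-value is below `alpha`.
#'
#' @param values numeric trait vector.
#' @param classes class label per value.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list: `anova` (F, p, df), `means` (class, n, mean, letters),
#'   `lsd` (pairwise class_a, class_b, diff, p).
#' @export
anova_lsd <- function(values, classes, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.character(classes)[keep]
  cnt <- table(classes)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("dropping class(es) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(classes %in% small)
    values <- values[keep]; classes <- classes[keep]
    cnt <- table(classes)
  }
  if (length(cnt) < 2)
    stop_named("invalid_argument", "need >= 2 classes with >= 2 members")
  f <- factor(classes)
  fit <- stats::lm(values ~ f)
  av <- stats::anova(fit)
  Fstat <- av$`F value`[1]; pval <- av$`Pr(>F)`[1]
  mse <- av$`Mean Sq`[2]; dfe <- av$Df[2]
  lev <- levels(f)
  mns <- tapply(values, f, mean)
  ns <- tapply(values, f, length)
  pairs <- utils::combn(lev, 2)
  lsd <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                    diff = NA_real_, t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- mns[[a]] - mns[[b]]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tt <- d / se
    lsd$diff[i] <- d
    lsd$t[i] <- tt
    lsd$p[i] <- 2 * stats::pt(-abs(tt), dfe)
  }
  letters <- .compact_letters(lev, lsd, alpha)
  means <- data.frame(class = lev, n = as.integer(ns[lev]),
                      mean = as.numeric(mns[lev]),
                      letters = letters[lev], stringsAsFactors = FALSE)
  means <- means[order(-means$mean), ]
  rownames(means) <- NULL
  list(anova = list(F = Fstat, p = pval, df = c(length(lev) - 1L, dfe),
                    mse = mse),
       means = means, lsd = lsd)
}

# insert-and-absorb compact letter display: classes sharing a letter are
# not significantly different at alpha
.compact_letters <- function(lev, lsd, alpha) {
  k <- length(lev)
  signif_pair <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(lsd))) {
    if (!is.na(lsd$p[i]) && lsd$p[i] < alpha) {
      signif_pair[lsd$class_a[i], lsd$class_b[i]] <- TRUE
      signif_pair[lsd$class_b[i], lsd$class_a[i]] <- TRUE
    }
  }
  groups <- list(lev)   # start with one letter covering everything
  for (a in lev) for (b in lev) {
    if (a < b && signif_pair[a, b]) {
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        if (all(c(a, b) %in% g)) {
          groups[[gi]] <- setdiff(g, a)
          groups[[length(groups) + 1L]] <- setdiff(g, b)
        }
      }
      # absorb: drop groups fully contained in another
      keep <- rep(TRUE, length(groups))
      for (i2 in seq_along(groups)) for (j2 in seq_along(groups)) {
        if (i2 != j2 && keep[i2] && keep[j2] &&
            all(groups[[i2]] %in% groups[[j2]])) keep[i2] <- FALSE
      }
      groups <- unique(groups[keep])
    }
  }
  lab <- stats::setNames(rep("", k), lev)
  for (gi in seq_along(groups)) {
    for (cl in groups[[gi]])
      lab[cl] <- paste0(lab[cl], letters[gi])
  }
  lab
}

#' Trait differences across the three genotype classes of one SNP
#'
#' Partitions accessions into hom-ref / het / hom-alt at a SNP and runs
#' [anova_lsd()] on the trait across the classes.
#'
#' @param G a [genotype_matrix()].
#' @param snp_id variant id or column index.
#' @param values per-accession trait vector aligned with `G$sample_ids`.
#' @param alpha LSD letter significance level.
#' @return list as from [anova_lsd()] plus `classes` (per-accession label).
#' @export
genotype_class_test <- function(G, snp_id, values, alpha = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- if (is.numeric(snp_id)) as.integer(snp_id)
         else match(snp_id, G$variants$id)
  if (is.na(idx)) stop_named("invalid_argument", "snp not present")
  d <- G$dosages[, idx]
  if (length(unique(d[!is.na(d)])) < 2)
    stop_named("monomorphic_snp", "SNP %s is monomorphic", snp_id)
  cls <- ifelse(is.na(d), NA, geno_code(d))
  res <- anova_lsd(values, cls, alpha = alpha)
  res$classes <- cls
  res
}

#' Genotype composition of phenotype groups at one SNP
#'
#' Per-group fractions of hom-ref / het / hom-alt calls, plus a Fisher
#' exact test of genotype x group association.
#'
#' @param G a [genotype_matrix()].
#' @param snp_id variant id or column index.
#' @param groups per-accession group label (e.g. resistance class).
#' @return list with `proportions` (group x genotype fractions), `counts`,
#'   and `fisher_p`.
#' @export
allele_composition <- function(G, snp_id, groups) {
  stopifnot(inherits(G, "genotype_matrix"),
            length(groups) == nrow(G$dosages))
  idx <- if (is.numeric(snp_id)) as.integer(snp_id)
         else match(snp_id, G$variants$id)
  if (is.na(idx)) stop_named("invalid_argument", "snp not present")
  d <- G$dosages[, idx]
  keep <- !is.na(d) & !is.na(groups)
  if (!length(unique(groups[keep])) || any(table(groups[keep]) == 0))
    stop_named("invalid_argument", "empty group")
  cls <- factor(geno_code(d[keep]), levels = c("R", "H", "A"))
  tab <- table(group = groups[keep], genotype = cls)
  if (any(rowSums(tab) == 0)) stop_named("invalid_argument", "empty group")
  prop <- sweep(tab, 1, rowSums(tab), "/")
  nonzero <- tab[, colSums(tab) > 0, drop = FALSE]
  fp <- if (nrow(nonzero) >= 2 && ncol(nonzero) >= 2)
    tryCatch(stats::fisher.test(nonzero, workspace = 2e7)$p.value,
             error = function(e)
               suppressWarnings(stats::chisq.test(nonzero)$p.value))
  else NA_real_
  list(proportions = prop, counts = tab, fisher_p = fp)
}
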