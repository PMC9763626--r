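test_that("haplotype classes concatenate genotype codes and exclude missing", {
  d <- rbind(c(0L, 0L), c(0L, 1L), c(2L, 2L), c(0L, NA), c(0L, 0L))
  G <- toy_genotypes(d)
  h <- build_haplotypes(G, 1:2)
  expect_equal(h$table$haplotype[1], "RR")
  expect_equal(h$table$haplotype[2], "RH")
  expect_equal(h$table$haplotype[3], "AA")
  expect_true(h$table$excluded[4])
  expect_equal(sum(h$freq$n), 4L)          # excluded accession not counted
  expect_equal(h$freq$freq[h$freq$haplotype == "RR"], 0.5)
  expect_error(build_haplotypes(G, integer(0)), class = "invalid_argument")

  # counting oracle on a simulated 5-SNP region
  cfg <- small_cfg(n_accessions = 150, missing_rate = 0.05, seed = 53)
  Gs <- simulate_genotypes(cfg)
  hs <- build_haplotypes(Gs, 11:15)
  codes <- apply(Gs$dosages[, 11:15], 1, function(x)
    if (anyNA(x)) NA else paste(c("R", "H", "A")[x + 1], collapse = ""))
  expect_equal(sort(hs$freq$n, decreasing = TRUE),
               sort(as.integer(table(codes)), decreasing = TRUE))
  # frequencies invariant to accession order
  perm <- sample(150)
  hp <- build_haplotypes(subset_snps(Gs, seq_len(ncol(Gs$dosages)), perm), 11:15)
  expect_equal(hp$freq, hs$freq)
})

test_that("ANOVA/LSD matches a from-scratch sums-of-squares oracle", {
  v <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  cl <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_lsd(v, cl)

  # oracle: explicit decomposition
  gm <- mean(v)
  mns <- tapply(v, cl, mean)
  ssb <- sum(3 * (mns - gm)^2)
  ssw <- sum((v - mns[cl])^2)
  msb <- ssb / 2; msw <- ssw / 6
  Fo <- msb / msw
  expect_equal(res$anova$F, Fo, tolerance = 1e-10)
  expect_equal(res$anova$p, pf(Fo, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  for (i in seq_len(nrow(res$lsd))) {
    a <- res$lsd$class_a[i]; b <- res$lsd$class_b[i]
    to <- (mns[[a]] - mns[[b]]) / sqrt(msw * (1 / 3 + 1 / 3))
    expect_equal(res$lsd$p[i], 2 * pt(-abs(to), 6), tolerance = 1e-10)
  }
  # letters: g1 and g2 share a letter, g3 is separate
  lets <- setNames(res$means$letters, res$means$class)
  expect_gt(length(intersect(strsplit(lets[["g1"]], "")[[1]],
                             strsplit(lets[["g2"]], "")[[1]])), 0)
  expect_equal(length(intersect(strsplit(lets[["g1"]], "")[[1]],
                                strsplit(lets[["g3"]], "")[[1]])), 0)
})

test_that("two identical groups share letters; two-class LSD equals the t-test", {
  v <- c(5, 6, 7, 5, 6, 7)
  cl <- rep(c("a", "b"), each = 3)
  res <- anova_lsd(v, cl)
  expect_lt(res$anova$F, 1e-20)
  expect_gt(length(intersect(strsplit(res$means$letters[1], "")[[1]],
                             strsplit(res$means$letters[2], "")[[1]])), 0)

  set.seed(59)
  v2 <- rnorm(14); cl2 <- rep(c("a", "b"), each = 7)
  r2 <- anova_lsd(v2, cl2)
  tt <- t.test(v2 ~ cl2, var.equal = TRUE)
  expect_equal(r2$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$lsd$p, tt$p.value, tolerance = 1e-10)
})

test_that("compact letters are consistent with the pairwise tests", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    v <- rnorm(12 * k, mean = rep(runif(k, 0, 3), each = 12))
    cl <- rep(letters[1:k], each = 12)
    res <- anova_lsd(v, cl)
    lets <- setNames(res$means$letters, res$means$class)
    for (r in seq_len(nrow(res$lsd))) {
      shared <- length(intersect(
        strsplit(lets[[res$lsd$class_a[r]]], "")[[1]],
        strsplit(lets[[res$lsd$class_b[r]]], "")[[1]])) > 0
      if (res$lsd$p[r] < 0.05) expect_false(shared)
      else expect_true(shared)
    }
  }
})

test_that("small classes are dropped with a warning", {
  v <- c(1, 2, 3, 4, 9)
  cl <- c("a", "a", "b", "b", "c")
  expect_warning(res <- anova_lsd(v, cl), "dropping class")
  expect_equal(sort(res$means$class), c("a", "b"))
  expect_error(suppressWarnings(anova_lsd(c(1, 2, 3), c("a", "a", "c"))),
               class = "invalid_argument")
})

test_that("genotype classes order trait means along an additive effect", {
  cfg <- small_cfg(n_accessions = 246, dsi_snp_pve = 0.5, replicate_sd = 0.1,
                   seed = 67)
  G <- simulate_genotypes(cfg)
  d <- compute_dsi(simulate_wilting(cfg, G))
  y <- d$dsi[match(G$sample_ids, d$accession)]
  res <- genotype_class_test(G, cfg$causal_dsi_snp, y)
  mns <- setNames(res$means$mean, res$means$class)[c("R", "H", "A")]
  expect_true(all(diff(mns) > 0) || all(diff(mns) < 0))
  expect_equal(sum(res$means$n), sum(!is.na(G$dosages[, cfg$causal_dsi_snp])))
  expect_error(genotype_class_test(toy_genotypes(cbind(rep(1L, 10))), 1,
                                   rnorm(10)),
               class = "monomorphic_snp")
})

test_that("null genotype-class P-values are uniform across seeds", {
  set.seed(71)
  ps <- vapply(1:60, function(s) {
    d <- c(rep(0L, 20), rep(1L, 20), rep(2L, 20))
    anova_lsd(rnorm(60), c("R", "H", "A")[d + 1])$anova$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("allele composition reports group fractions and association", {
  d <- cbind(c(rep(2L, 10), rep(0L, 10)))
  G <- toy_genotypes(d)
  grp <- rep(c("R", "S"), each = 10)
  ac <- allele_composition(G, 1, grp)
  expect_equal(ac$proportions["R", "A"], 1.0)
  expect_equal(ac$proportions["S", "R"], 1.0)
  expect_true(all(abs(rowSums(ac$proportions) - 1) < 1e-12))
  expect_lt(ac$fisher_p, 0.05)

  # strongly associated planted SNP is detected in most seeds
  hits <- vapply(1:10, function(s) {
    cfg <- small_cfg(n_accessions = 246, dsi_snp_pve = 0.5,
                     replicate_sd = 0.1, seed = 900 + s)
    G <- simulate_genotypes(cfg)
    cl <- classify_extremes(compute_dsi(simulate_wilting(cfg, G)), 20)
    grp <- cl$resistance_class[match(G$sample_ids, cl$accession)]
    ext <- grp %in% c("R", "S")
    Ge <- subset_snps(G, cfg$causal_dsi_snp, ext)
    tryCatch(allele_composition(Ge, 1, grp[ext])$fisher_p < 0.05,
             error = function(e) NA)
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
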