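test_that("genotype simulation is deterministic and respects the config", {
  cfg <- small_cfg(seed = 11)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$dosages, G2$dosages)
  expect_identical(G1$variants, G2$variants)
  G3 <- simulate_genotypes(small_cfg(seed = 12))
  expect_false(identical(G1$dosages, G3$dosages))

  expect_false(anyNA(simulate_genotypes(small_cfg(missing_rate = 0))$dosages))
  Gm <- simulate_genotypes(small_cfg(missing_rate = 0.08, seed = 2))
  expect_gt(mean(is.na(Gm$dosages)), 0.05)
  # positions strictly increasing per chromosome (constructor invariant)
  for (ch in unique(G1$variants$chrom))
    expect_false(is.unsorted(G1$variants$pos[G1$variants$chrom == ch],
                             strictly = TRUE))
})

test_that("fst = 0 leaves subpopulation frequencies at the pooled frequency", {
  cfg <- small_cfg(n_accessions = 300, n_snps = 280, fst = 0,
                   missing_rate = 0, seed = 21)
  G <- simulate_genotypes(cfg)
  sub <- attr(G, "subpop")
  p_pool <- colMeans(G$dosages) / 2
  # binomial sampling oracle: subpop frequency within 3 SE of pooled for
  # >= 95% of SNP x subpop combinations
  ok <- 0; tot <- 0
  for (k in unique(sub)) {
    nk <- sum(sub == k)
    pk <- colMeans(G$dosages[sub == k, , drop = FALSE]) / 2
    se <- sqrt(pmax(p_pool * (1 - p_pool), 1e-9) / (2 * nk))
    ok <- ok + sum(abs(pk - p_pool) < 3 * se)
    tot <- tot + length(pk)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("structured genotypes give block-structured kinship", {
  cfg <- small_cfg(n_accessions = 120, n_snps = 350, fst = 0.25, seed = 5)
  G <- simulate_genotypes(cfg)
  K <- kinship(G)
  sub <- attr(G, "subpop")
  same <- outer(sub, sub, "==") & !diag(length(sub))
  expect_gt(mean(K[same]), mean(K[!same & !diag(length(sub))]))
})

test_that("retained SNPs match the configured frequency range after filtering", {
  cfg <- small_cfg(n_accessions = 246, n_snps = 350, seed = 9)
  Gf <- filter_variants(simulate_genotypes(cfg), maf_min = 0.05)
  p <- colMeans(Gf$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  expect_true(all(maf >= 0.05 & maf <= 0.5))
  expect_gt(ncol(Gf$dosages), 0.5 * cfg$n_snps)
})

test_that("null metabolites show the theoretical squared-correlation tail", {
  cfg <- small_cfg(n_accessions = 246, n_snps = 140, n_metabolites = 30,
                   missing_rate = 0, seed = 31)
  G <- simulate_genotypes(cfg)
  met <- simulate_metabolites(cfg, G, h2 = rep(0, 30))
  L <- log2(met$ck$abundances)
  r2 <- as.vector(cor(L, G$dosages))^2
  n <- nrow(L)
  # under the null, r^2 ~ Beta(1/2, (n-2)/2)
  expect_lt(abs(quantile(r2, 0.95) - qbeta(0.95, 1 / 2, (n - 2) / 2)), 0.006)
})

test_that("planted QTL effect sizes reproduce the target PVE", {
  r2 <- vapply(1:15, function(s) {
    cfg <- small_cfg(n_accessions = 246, n_snps = 140, n_metabolites = 2,
                     planted_qtls = data.frame(snp = 70, metabolite = 1,
                                               pve = 0.15),
                     seed = 40 + s)
    G <- simulate_genotypes(cfg)
    met <- simulate_metabolites(cfg, G)
    x <- G$dosages[, 70]; x[is.na(x)] <- mean(x, na.rm = TRUE)
    summary(lm(log2(met$ck$abundances[, 1]) ~ x))$r.squared
  }, 0)
  expect_lt(abs(mean(r2) - 0.15), 0.05)
})

test_that("induction shifts reproduce the configured fold change", {
  cfg <- small_cfg(n_accessions = 246, n_snps = 140, n_metabolites = 20,
                   n_inducible = 6, seed = 51)
  G <- simulate_genotypes(cfg)
  met <- simulate_metabolites(cfg, G, h2 = rep(0.9, 20))  # low residual noise
  tr <- met$truth
  gm_ratio <- 2^(colMeans(log2(met$ds$abundances)) -
                   colMeans(log2(met$ck$abundances)))
  for (j in tr$inducible_features) {
    expect_lt(abs(log2(gm_ratio[j]) - log2(tr$true_induction_fc[j])), 0.15)
  }
  # non-inducible features do not shift
  quiet <- setdiff(seq_len(20), tr$inducible_features)
  expect_true(all(abs(log2(gm_ratio[quiet])) < 0.15))
  # total planted PVE + background h2 > 1 is rejected
  expect_error(
    small_cfg(n_metabolites = 2, n_snps = 140,
              planted_qtls = data.frame(snp = 1, metabolite = 1, pve = 1.2)),
    class = "invalid_argument")
})

test_that("wilting liabilities link grades to the causal SNP as configured", {
  # zero causal effect: DSI uncorrelated with the causal dosage
  cfg0 <- small_cfg(n_accessions = 246, n_snps = 140, dsi_snp_pve = 0,
                    seed = 61)
  G <- simulate_genotypes(cfg0)
  d <- compute_dsi(simulate_wilting(cfg0, G))
  x <- G$dosages[, cfg0$causal_dsi_snp]
  keep <- !is.na(x)
  expect_lt(abs(cor(d$dsi[keep], x[keep])), 0.15)

  # grades are monotone in time on cohort average
  gr <- simulate_wilting(small_cfg(n_accessions = 200, n_snps = 140, seed = 62),
                         simulate_genotypes(small_cfg(n_accessions = 200,
                                                      n_snps = 140, seed = 62)))
  mg <- tapply(gr$grade, gr$timepoint_h, mean, na.rm = TRUE)
  expect_true(mg[["96"]] >= mg[["72"]] && mg[["120"]] >= mg[["96"]])

  # strong effect, low noise: risk homozygotes end up in the top DSI tercile
  hits <- vapply(1:10, function(s) {
    cfg <- small_cfg(n_accessions = 246, n_snps = 140, dsi_snp_pve = 0.6,
                     replicate_sd = 0.1, seed = 70 + s)
    G <- simulate_genotypes(cfg)
    d <- compute_dsi(simulate_wilting(cfg, G))
    x <- G$dosages[, cfg$causal_dsi_snp]
    liab <- attr(simulate_wilting(cfg, G), "liability")
    risk_hom <- which(!is.na(x) & x == (if (cor(liab, x, use = "complete") > 0) 2 else 0))
    top <- d$dsi >= quantile(d$dsi, 2 / 3, na.rm = TRUE)
    mean(top[risk_hom]) > 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("NA injection appears only when configured", {
  cfg <- small_cfg(seed = 81)
  expect_false(anyNA(simulate_wilting(cfg, simulate_genotypes(cfg))$grade))
  cfg_na <- small_cfg(na_rate = 0.1, seed = 81)
  gr <- simulate_wilting(cfg_na, simulate_genotypes(cfg_na))
  expect_gt(mean(is.na(gr$grade)), 0.05)
})

test_that("the simulated VCF round-trips with zero dosage mismatches", {
  cfg <- small_cfg(missing_rate = 0.05, seed = 91)
  G <- simulate_genotypes(cfg)
  f <- tempfile(fileext = ".vcf")
  write_vcf(G, f)
  G2 <- read_vcf(f)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$variants$pos, G$variants$pos)
  # byte-identical output for a fixed seed
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_genotypes(cfg), f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})
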