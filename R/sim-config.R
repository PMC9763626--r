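#' Configuration for the synthetic drought cohort
#'
#' Bundles every parameter of the synthetic cohort generator. The defaults
#' describe a structured highland-barley-like panel: 246 accessions in six
#' subpopulations (Fst 0.1), biallelic SNPs with ancestral MAF in
#' [0.05, 0.5] and 2\% missing calls, first-order-Markov LD blocks of ten
#' SNPs (copy probability 0.9), metabolite features with broad-sense
#' heritability averaging 0.5, one planted metabolite QTL explaining 15\% of
#' phenotypic variance, drought-induction fold changes between 1.5x and 5x,
#' and a single causal SNP driving the wilting liability.
#'
#' @param n_accessions number of accessions (diploid individuals).
#' @param n_snps total number of SNPs, split evenly across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_subpops number of subpopulations (>= 1).
#' @param fst divergence of subpopulation allele frequencies from the
#'   ancestral frequency under the Balding-Nichols model; 0 means a single
#'   panmictic population.
#' @param maf_range range of the ancestral allele frequency draw, within
#'   (0, 0.5].
#' @param missing_rate fraction of genotype calls set to missing.
#' @param ld_block_len number of consecutive SNPs forming one LD block.
#' @param ld_copy_prob probability that a haplotype copies the previous
#'   SNP's allele within a block (first-order Markov LD).
#' @param n_metabolites number of metabolite features.
#' @param h2_mean mean broad-sense heritability of the metabolite features
#'   (per-feature values are drawn from a Beta distribution with this mean).
#' @param planted_qtls data.frame with columns `snp`, `metabolite`, `pve`:
#'   metabolite QTLs to plant, each explaining `pve` of that feature's
#'   variance. `NULL` plants one QTL with PVE 0.15 on feature 1 at a SNP in
#'   the middle of chromosome 2.
#' @param n_inducible number of drought-inducible features (cohort-wide
#'   abundance shift between control, CK, and drought stress, DS).
#' @param induction_log2fc_range magnitude range of the induction effect on
#'   the log2 scale; defaults to fold changes of 1.5x to 5x.
#' @param n_constitutive number of constitutively R/S-differential features
#'   (stable resistant-vs-sensitive difference in both conditions).
#' @param constitutive_log2diff log2 difference (resistant minus sensitive)
#'   for constitutive features.
#' @param causal_dsi_snp index of the SNP whose dosage drives the wilting
#'   liability; `NULL` picks a block-centered SNP in the middle of
#'   chromosome 1.
#' @param dsi_snp_pve fraction of the liability variance explained by the
#'   causal SNP (0 disables the genetic effect).
#' @param n_replicates biological replicates per accession for wilting
#'   counts.
#' @param total_leaves leaves counted per replicate (15 plants x 3 leaves).
#' @param replicate_sd standard deviation of the replicate-level liability
#'   noise (the within-accession consistency of wilting is a free
#'   parameter).
#' @param rate_slope logit-scale slope mapping liability to the latent
#'   wilting rate; together with `timepoint_shift` it sets the cohort DSI
#'   mean and coefficient of variation (defaults reproduce a mean near 2.05
#'   and a CV near 50\%).
#' @param timepoint_shift logit-scale shift of the wilting rate at 72, 96
#'   and 120 h; must be non-decreasing so wilting severity grows with time.
#' @param na_rate fraction of replicate x timepoint wilting observations
#'   recorded as NA (low-germination replicates); default none.
#' @param k_extremes number of extreme resistant (R) and sensitive (S)
#'   accessions selected from the DSI ranking.
#' @param seed integer seed; the seed fully determines all outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 246,
                       n_snps = 3500,
                       n_chromosomes = 7,
                       chrom_length_bp = 2e7,
                       n_subpops = 6,
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       ld_block_len = 10,
                       ld_copy_prob = 0.9,
                       n_metabolites = 120,
                       h2_mean = 0.5,
                       planted_qtls = NULL,
                       n_inducible = 10,
                       induction_log2fc_range = log2(c(1.5, 5)),
                       n_constitutive = 10,
                       constitutive_log2diff = 1,
                       causal_dsi_snp = NULL,
                       dsi_snp_pve = 0.3,
                       n_replicates = 3,
                       total_leaves = 45,
                       replicate_sd = 0.3,
                       rate_slope = 2.2,
                       timepoint_shift = c(-2.2, -0.7, 0.6),
                       na_rate = 0,
                       k_extremes = 20,
                       seed = 1) {
  cfg <- list(
    n_accessions = check_count(n_accessions, "n_accessions", 2L),
    n_snps = check_count(n_snps, "n_snps"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    chrom_length_bp = check_count(chrom_length_bp, "chrom_length_bp"),
    n_subpops = check_count(n_subpops, "n_subpops"),
    fst = check_fraction(fst, "fst", 0, 1, hi_open = TRUE),
    maf_range = maf_range,
    missing_rate = check_fraction(missing_rate, "missing_rate"),
    ld_block_len = check_count(ld_block_len, "ld_block_len"),
    ld_copy_prob = check_fraction(ld_copy_prob, "ld_copy_prob"),
    n_metabolites = check_count(n_metabolites, "n_metabolites"),
    h2_mean = check_fraction(h2_mean, "h2_mean", 0, 1, hi_open = TRUE),
    planted_qtls = planted_qtls,
    n_inducible = check_count(n_inducible, "n_inducible", 0L),
    induction_log2fc_range = induction_log2fc_range,
    n_constitutive = check_count(n_constitutive, "n_constitutive", 0L),
    constitutive_log2diff = constitutive_log2diff,
    causal_dsi_snp = causal_dsi_snp,
    dsi_snp_pve = check_fraction(dsi_snp_pve, "dsi_snp_pve", 0, 1, hi_open = TRUE),
    n_replicates = check_count(n_replicates, "n_replicates"),
    total_leaves = check_count(total_leaves, "total_leaves"),
    replicate_sd = check_fraction(replicate_sd, "replicate_sd", 0, Inf),
    rate_slope = check_fraction(rate_slope, "rate_slope", 0, Inf, lo_open = TRUE),
    timepoint_shift = timepoint_shift,
    na_rate = check_fraction(na_rate, "na_rate", 0, 1, hi_open = TRUE),
    k_extremes = check_count(k_extremes, "k_extremes", 0L),
    seed = check_count(seed, "seed", 0L)
  )
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_named("invalid_argument", "maf_range must be within (0, 0.5]")
  if (length(cfg$timepoint_shift) != 3 || is.unsorted(cfg$timepoint_shift))
    stop_named("invalid_argument", "timepoint_shift must be 3 non-decreasing values")
  if (is.null(cfg$causal_dsi_snp)) {
    # block-centred SNP in the middle of chromosome 1 so that LD neighbours
    # flank it on both sides
    per_chrom <- cfg$n_snps %/% cfg$n_chromosomes
    mid <- per_chrom %/% 2
    cfg$causal_dsi_snp <- as.integer(
      (mid %/% cfg$ld_block_len) * cfg$ld_block_len + cfg$ld_block_len %/% 2 + 1)
  }
  if (cfg$causal_dsi_snp > cfg$n_snps)
    stop_named("invalid_argument", "causal_dsi_snp exceeds n_snps")
  if (is.null(cfg$planted_qtls)) {
    per_chrom <- cfg$n_snps %/% cfg$n_chromosomes
    mid2 <- per_chrom + per_chrom %/% 2   # middle of chromosome 2
    snp2 <- as.integer((mid2 %/% cfg$ld_block_len) * cfg$ld_block_len +
                         cfg$ld_block_len %/% 2 + 1)
    cfg$planted_qtls <- data.frame(snp = min(snp2, cfg$n_snps),
                                   metabolite = 1L, pve = 0.15)
  }
  pq <- cfg$planted_qtls
  if (nrow(pq)) {
    stopifnot(all(c("snp", "metabolite", "pve") %in% names(pq)))
    if (any(pq$pve <= 0 | pq$pve >= 1))
      stop_named("invalid_argument", "planted pve must be in (0, 1)")
    if (any(pq$snp > cfg$n_snps) || any(pq$metabolite > cfg$n_metabolites))
      stop_named("invalid_argument", "planted QTL indices out of range")
  }
  if (cfg$n_inducible + cfg$n_constitutive > cfg$n_metabolites)
    stop_named("invalid_argument",
               "n_inducible + n_constitutive exceeds n_metabolites")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d accessions, %d SNPs on %d chromosomes, %d subpops (Fst %.2f)\n",
    x$n_accessions, x$n_snps, x$n_chromosomes, x$n_subpops, x$fst))
  cat(sprintf("  %d metabolites (mean H2 %.2f), %d planted QTL(s), seed %d\n",
              x$n_metabolites, x$h2_mean, nrow(x$planted_qtls), x$seed))
  invisible(x)
}
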