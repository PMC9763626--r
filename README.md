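# qkmgwas

Drought-resistance phenotyping and metabolite GWAS for structured crop
cohorts, modelled on the analysis of qingke (Tibetan hulless barley,
*Hordeum vulgare* L. var. *nudum*) diversity panels.

## The problem

Seedling drought resistance in a diversity panel is scored by counting
wilted leaves under stress: the wilting rate per replicate is binned into
ordinal grades 0–4 at 72, 96 and 120 h, and the **drought-sensitivity
index** is

    DSI = (Grade72h + Grade96h + Grade120h) / 3,

with lower values indicating stronger resistance. Resistant (R) and
sensitive (S) extremes are taken from the tails of the DSI ranking. The
genetic basis of DSI and of thousands of metabolite abundances (measured
under control, CK, and drought stress, DS) is mapped with the linear mixed
model

    y = X b + g + e,   g ~ N(0, σ²_g K),   e ~ N(0, σ²_e I),

where `y` is DSI or a log2 metabolite abundance, `X` holds an intercept and
principal-component structure covariates, and `K` is the centred realised
kinship matrix. Variance components are estimated by REML after a single
eigendecomposition of `K`; each SNP is then tested by generalized least
squares, with the Wald statistic referred to F(1, n−q−1). Significance uses
an effective-SNP Bonferroni threshold (e.g. 0.05 / 1,174,039 ≈ 4.26e-08 for
an LD-pruned set of that size); significant SNPs less than 1 Mb apart are
chained into loci, chains spanning more than 30 Mb are abandoned, loci with
fewer than six member SNPs are discarded, and the lowest-P member is the
lead SNP. Differential metabolites combine PLS-DA VIP > 1.0, fold change
≥ 1.5 or ≤ 0.67, and Benjamini–Hochberg-adjusted Student's *t* P < 0.05;
features are further classified as drought-**inducible** (cohort-wide
DS-vs-CK response) or **constitutive-differential** (stable R-vs-S
difference in both conditions). Haplotype classes built from genotype codes
are compared by one-way ANOVA with Fisher's protected LSD and compact
letters.

Because the original cohort's raw data are not redistributable at desk
scale, the package ships a population-structure-aware synthetic cohort
generator (Balding–Nichols subpopulations, Markov LD blocks, planted
metabolite QTLs, liability-driven wilting grades) with a ground-truth
ledger, so every stage is testable end to end.

## Worked example

```r
library(qkmgwas)

cfg    <- sim_config(n_snps = 1400, n_metabolites = 20, seed = 3)
cohort <- simulate_cohort(cfg)

dsi_summary(cohort$dsi)[c("mean", "cv")]
#> $mean
#> [1] 1.982836
#> $cv
#> [1] 0.5730982

Gf   <- filter_variants(cohort$genotypes)          # MAF >= 0.05, MCF <= 0.1
kept <- ld_prune(Gf)                               # 50-SNP windows, r2 > 0.2
K    <- kinship(Gf)
Q    <- structure_covariates(subset_snps(Gf, kept), 6)
y    <- cohort$dsi$dsi[match(Gf$sample_ids, cohort$dsi$accession)]

fit <- fit_null_lmm(y, K, Q)
fit
#> lmm_fit (REML): sigma_g2 = 0.3343, sigma_e2 = 0.8836, pseudo-h2 = 0.274
#>   delta = 2.643, loglik = -356.239, n = 246, covariates = 7

assoc <- wald_scan(Gf, fit)
thr   <- bonferroni_threshold(0.05, length(kept))
cluster_loci(assoc, threshold = thr, trait = "DSI")
#>   trait chrom   start      end n_snps      lead_snp lead_pos       lead_p
#> 1   DSI chr1H 9534507 10274950     10 chr1H:9931518  9931518 7.900924e-17
```

The single DSI locus on chr1H contains ten significant SNPs and its lead
SNP, `chr1H:9931518`, is exactly the SNP the simulator planted as the
causal wilting-liability variant — the scan, thresholding and locus rules
recover the planted architecture. The pseudo-heritability (0.27) is the
REML share of DSI variance attributable to the kinship random effect.

`run_pipeline(list(seed = 3), "out/")` executes the whole flow
(simulation → DSI scoring → QC → kinship/PCs → mixed-model scan → loci →
metabolite differential calling and classification → haplotype tests) and
writes TSV/VCF/Newick/JSON outputs with provenance headers.

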