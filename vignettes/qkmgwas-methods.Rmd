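---
title: "Models and methods in qkmgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in qkmgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qkmgwas)
```

qkmgwas implements a complete drought-resistance dissection workflow for
structured crop panels: ordinal wilting phenotyping, variant QC, a linear
mixed-model association scan, locus aggregation, metabolomics statistics,
haplotype association, and a synthetic cohort generator that makes the
whole chain testable against known truth. This vignette records the models,
the parameters that matter, and the design decisions taken where the
methodology was genuinely open.

## Phenotype model

Wilting rates (wilted leaves / total leaves, typically 45 leaves from 15
plants) are binned into grades: 0 for a rate of exactly 0, then the
half-open intervals (0, 0.25], (0.25, 0.5], (0.5, 0.75], (0.75, 1] for
grades 1–4. The conventional bin phrasing in whole percent ("1% to 25%", ...)
presumes integer
percentages; half-open intervals extend it consistently to fractional
rates, keeping the map single-valued and monotone. Grading happens per
replicate and grades are then averaged — replicates first within each
timepoint, then across the three timepoints — giving the
drought-sensitivity index DSI = (G72 + G96 + G120)/3 on [0, 4]. A timepoint
whose replicates are all missing (low germination) voids the DSI for that
accession; partial missingness is tolerated. Extreme-group selection is a
pure DSI ranking (k lowest = R, k highest = S, ties broken by accession
identifier); field screens often also weigh between-replicate consistency
subjectively, replaced here by an optional replicate-SD cap, off by
default.

## Mixed-model scan

The association model is y = Xb + g + e with g ~ N(0, σ²_g K) and
e ~ N(0, σ²_e I). `kinship()` returns the centred cross-product
K = X_c X_c'/m. Before fitting, `fit_null_lmm()` rescales K to mean
diagonal 1 (the usual GRM normalisation), so that the REML pseudo-
heritability σ²_g/(σ²_g + σ²_e) is on the marginal-variance scale; this is
what makes recovery of a planted heritability a well-posed check. K is
eigendecomposed once; the variance ratio δ = σ²_e/σ²_g is profiled out of
the restricted likelihood and located by a deterministic 100-point log-grid
scan over [1e-5, 1e5] followed by Brent refinement — no random restarts, so
fits are reproducible to machine precision.

Each SNP is tested by GLS in the rotated space. The default *approximate*
mode reuses the null δ for every SNP (the standard fast variant); `exact =
TRUE` re-optimises δ per SNP, and the two agree to |Δlog10 p| < 0.3 on null
panels at n = 246 (tested). The Wald statistic is referred to
F(1, n − q − 1) rather than χ²₁: the finite-sample F reference reduces
*exactly* to the ordinary regression t-test when K = I, which is the
oracle-equivalence property the test suite asserts at a relative tolerance
of 1e-6; the two references agree asymptotically. Missing dosages are
mean-imputed per SNP; monomorphic SNPs are flagged and reported with
β = 0, p = 1. Per-SNP variance explained uses the conventional marginal
definition PVE = β² Var(x)/Var(y), clipped to [0, 1] — no formula is
canonical here, so the definition is validated by recovery of planted PVE
targets (±0.05 at a true 0.15, n = 246). Population structure enters as
principal-component covariates of the standardized, LD-pruned dosage
matrix (default 6 components, mirroring a six-group ancestry model);
model-based admixture estimation is out of scope and PCs are the standard
LMM proxy.

At desk scale a planted QTL's LD block is a non-negligible share of a
few-hundred-SNP kinship, and the full-kinship scan absorbs part of the
causal signal (proximal contamination): measured detection power at PVE
0.15 was roughly 0.35 with all-SNP kinship versus 0.90 with
leave-one-chromosome-out kinship. At realistic marker counts (millions of
SNPs) one block is a negligible share of K, so LOCO —
`kinship(G, exclude_chrom = )`, standard mixed-model practice — is the
faithful analogue and is what the recovery checks use.

## Locus rules

Significant SNPs (P at or below the effective-SNP Bonferroni threshold,
α divided by the LD-pruned SNP count) are chained single-linkage: adjacent
significant SNPs on one chromosome join a locus when their gap is below
1 Mb; a chain spanning more than 30 Mb is abandoned *with its SNPs* (the
alternative — releasing them for re-chaining — re-creates the same
over-long chain, so discarding is the only consistent reading); loci with
fewer than six members are dropped ("more than five" read strictly as
≥ 6). The lead SNP is the lowest-P member, ties broken by smallest
position. Locus boundaries are the min/max member positions, the least-committal
interval definition. Colocalization between
locus sets is plain interval intersection on a shared chromosome. All of
this is fuzz-tested (1,000 random inputs) against an independently coded
brute-force reference.

## Metabolomics statistics

Raw abundances are strictly positive; tests run on log2 values, fold
changes on raw group means (the convention of the standard differential
workflow), and min-max normalisation is available for clustering displays.
PLS-DA uses NIPALS with a centred ±1 dummy response on autoscaled
features, two components by default (two components with unit-variance scaling is
the common default, and the implementation agrees with an independent PLS-DA
implementation to machine precision in the test suite). VIP scores satisfy
Σ VIP² = p exactly, which the suite asserts on every run. A feature is
called differential when VIP > 1.0, FC ≥ 1.5 or ≤ 0.67, and adjusted
t-test P < 0.05; "adjusted" is read as Benjamini–Hochberg across features
(the default of the standard implementations; Bonferroni is available), and the t-test is
the classic pooled-variance Student test (Welch and paired variants are
options; unpaired is the default, with CK/DS pairing by accession
available).

The four-group framework reports per-feature fold changes for R_DS/R_CK,
S_DS/S_CK (induction within resistance groups) and R_CK/S_CK, R_DS/S_DS
(constitutive differences within conditions), with rank-sum tests
comparing |log2 FC| distributions between contrasts. Feature classes
combine three call sets: *inducible* = called cohort-wide DS-vs-CK only;
*constitutive_differential* = called in the same direction R-vs-S under
both conditions but not cohort-wide; *both* and *neither* complete the
partition.

Sample trees binarise each feature at its cohort median (the
least-informative monotone way to turn continuous abundances into
match/mismatch states), compute the
simple matching distance, and apply standard neighbor joining (negative
branch lengths clamped to zero). Spearman correlation matrices use
tie-corrected ranks with t-approximation P-values, BH-adjusted over the
upper triangle.

## Haplotype association

Multi-SNP haplotype classes concatenate per-SNP genotype codes (hom-ref /
het / hom-alt) rather than phased alleles — phasing is unavailable, so
heterozygous carriers form their own class at every constituent SNP.
Accessions missing any
constituent SNP are excluded from frequencies. Group comparisons use
one-way ANOVA followed by Fisher's protected LSD: pairwise t-tests sharing
the pooled within-group mean square and its degrees of freedom, with no
multiplicity correction (the procedure's definition; protection comes from
the omnibus F). Compact letters are assigned by insert-and-absorb so that
two classes share no letter exactly when their LSD P-value is below α;
with two classes the procedure reduces exactly to the pooled t-test
(F = t²), which the suite asserts.

## The synthetic cohort generator

The generator's defaults are the study conditions it emulates: 246
accessions in six subpopulations at Fst 0.1 (Balding–Nichols allele
frequencies), seven chromosomes, ancestral MAF uniform on [0.05, 0.5], 2%
missing calls (≤ 10% tolerated by QC), LD blocks of ten SNPs built by
first-order Markov copying with probability 0.9, metabolite features with
broad-sense heritability drawn from a Beta with mean 0.5, one planted
metabolite QTL with PVE 0.15, drought-induction fold changes uniform
between 1.5× and 5× (random sign), and a single causal SNP explaining 30%
of the wilting liability. Genetic effects are injected on the log2 scale so
fold-change statistics and GWAS operate on the scales the analyses assume;
the polygenic term is drawn through the square root of the realised,
trace-normalised kinship, which is what makes pseudo-heritability recovery
well-posed. The DS condition shares the genetic components with CK (the
same plants' genetics), draws an independent residual, and adds the
induction shift plus group-specific constitutive offsets.

Wilting counts are binomial draws around a logistic latent rate,
`plogis(slope · (liability + replicate noise) + shift_t)`, with
non-decreasing timepoint shifts so severity grows with time. The slope and
shifts (2.2; −2.2, −0.7, 0.6) were calibrated once so the simulated cohort
sits in a realistic qingke-panel DSI regime (mean ≈ 2.05, CV ≈ 50%, and a 72-h
grade-≤1 share near 57%); the within-accession replicate noise SD (0.3) is
a free parameter, as replicate variance was not reported. Default
chromosome length is 20 Mb with ~500 SNPs per chromosome (≈ 40 kb
spacing): scaled down from millions of markers, this keeps the marker
spacing far below the 1 Mb locus-merge window, preserving the regime in
which the chaining rules were formulated.

What the generator does *not* emulate: mass-spectral artefacts (missing
features, batch effects, nonlinear intensity response), realistic
recombination maps or long-range LD, genotype calling error, and selection
or kinship beyond the subpopulation block structure. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to those real-data complications.

## Numerical choices and problem sizes

Variance-ratio optimisation is grid-plus-Brent, deterministic; eigenvalues
clipped at zero; rank-deficient covariates rejected. LD pruning removes the
lower-MAF member of an offending pair (ties drop the later position),
matching the pairwise convention of the standard pruning tool, with
pairwise-complete correlations under missingness. Nucleotide diversity uses
the unbiased per-site estimator 2p̂(1−p̂)·2N/(2N−1) summed over a window
and divided by the window *length* in bp (windowed-diversity tool
convention; 0-based half-open coordinates in the BED-like output only).
Fisher exact tests fall back to a chi-square approximation only when the
exact network algorithm is infeasible. The random-number streams are
derived from one global seed via fixed per-stage offsets, so adding a stage
never shifts another stage's draws.

Test and acceptance problem sizes are scaled for a desk run while keeping
n = 246 wherever the cohort size matters statistically: panels of 700–4,200
SNPs, 1–120 metabolite features, 50 seeds for detection power, 25 for
heritability recovery, and calibration pooled over eight permuted
phenotypes (~32,000 tests) because a single fixed phenotype vector
contributes conditional-on-y fluctuation of about ±0.01 to the rejection
fraction on its own. Null calibration is evaluated on MAF-filtered markers,
matching the standard pre-GWAS filter; a mild residual conservatism
(rejection fraction ≈ 0.046 at the 0.05 level) reflects the finite-sample
behaviour of discrete low-MAF regressors against a fixed phenotype.

## Known limitations

Broad-sense heritability of metabolite features is reported as REML
pseudo-heritability from the null mixed model — a marker-based proxy, not
a replicate-based estimate — and labelled as such. Where the field leaves
conventions open (locus interval definition, haplotype frequency
denominators, CK/DS test pairing), the choices made are documented above
and in the function reference. The scan is single-trait only, and no
candidate-gene annotation is attempted — locus coordinates are the
endpoint.
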