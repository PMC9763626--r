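Package: qkmgwas
Title: Drought-Resistance Phenotyping and Metabolite GWAS for Structured Crop Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting drought resistance in structured crop panels
    such as qingke (Tibetan hulless barley). Implements wilting-grade scoring and
    the drought-sensitivity index (DSI), variant QC (MAF/missingness filters,
    sliding-window LD pruning, centered kinship, PCA structure covariates,
    windowed nucleotide diversity), an exact/approximate linear mixed-model
    association scan with REML variance components, per-SNP phenotypic variance
    explained and effective-SNP significance thresholds, locus clustering with
    lead-SNP selection and hotspot/colocalization summaries, metabolomics
    statistics (PLS-DA with VIP, fold-change/adjusted-t differential calling,
    inducible versus constitutive classification, Spearman correlation networks,
    neighbor-joining sample trees), haplotype association with one-way ANOVA and
    Fisher LSD, and a population-structure-aware synthetic cohort generator with
    a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
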