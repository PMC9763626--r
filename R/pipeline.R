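#' Run the full drought-resistance analysis pipeline
#'
#' Orchestrates the stages on a synthetic cohort (or user-supplied inputs):
#' cohort simulation, DSI scoring, variant QC, LD pruning, kinship and
#' structure covariates, the mixed-model DSI scan, locus clustering, the
#' metabolomics differential/classification stages, and the haplotype test
#' at the causal SNP. Every tabular output carries '#'-prefixed provenance
#' lines (package version, config hash, seed), and a run log records each
#' stage with its parameters and row counts. A single global seed is
#' expanded into per-stage sub-streams, so the results are reproducible
#' byte-for-byte for a given config.
#'
#' @param config a named list (or path to a YAML file) with optional
#'   entries: `seed` (default 1), `sim` (arguments to [sim_config()]),
#'   `k_extremes`, `maf_min`, `mcf_max`, `prune` (window/step/r2_max),
#'   `n_pcs`, `alpha`, `loci` (merge_bp/max_span_bp/min_snps),
#'   `with_metabolites` (default TRUE).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohort`, `assoc`,
#'   `loci`, `threshold`, `diff`, `classes`, `log`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  if (!is.null(config$k_extremes)) sim_args$k_extremes <- config$k_extremes
  cfg <- do.call(sim_config, sim_args)

  # validate stage parameters before any stage runs
  maf_min <- config$maf_min %||% 0.05
  mcf_max <- config$mcf_max %||% 0.1
  check_fraction(maf_min, "maf_min", 0, 0.5)
  check_fraction(mcf_max, "mcf_max")
  prune_par <- utils::modifyList(list(window = 50, step = 5, r2_max = 0.2),
                                 config$prune %||% list())
  n_pcs <- check_count(config$n_pcs %||% 6, "n_pcs")
  alpha <- config$alpha %||% 0.05
  check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  loci_par <- utils::modifyList(list(merge_bp = 1e6, max_span_bp = 3e7,
                                     min_snps = 6), config$loci %||% list())
  with_met <- config$with_metabolites %||% TRUE

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  cfg_hash <- substr(unname(tools::md5sum(cfg_file)), 1, 8)
  prov <- c(sprintf("qkmgwas %s", as.character(utils::packageVersion("qkmgwas"))),
            sprintf("config_hash %s", cfg_hash),
            sprintf("seed %d", seed))

  log <- list()
  note <- function(stage, params, n_in, n_out, status = "ok") {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, params = params, n_in = n_in, n_out = n_out,
      status = status, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_named("stage_failed", "stage '%s' failed: %s", stage,
                 conditionMessage(e))
    })
  }

  # --- simulate -------------------------------------------------------
  cohort <- run_stage("simulate", simulate_cohort(cfg))
  G <- cohort$genotypes
  write_vcf(G, file.path(out_dir, "genotypes.vcf"))
  write_tsv(cohort$grades, file.path(out_dir, "grades.tsv"), prov)
  write_truth_json(cohort$truth, file.path(out_dir, "truth.json"))
  note("simulate", sprintf("n=%d m=%d", cfg$n_accessions, cfg$n_snps),
       NA, nrow(G$dosages))

  # --- phenotype scoring ---------------------------------------------
  dsi <- cohort$dsi
  write_tsv(dsi, file.path(out_dir, "dsi.tsv"), prov)
  note("score_dsi", sprintf("k_extremes=%d", cfg$k_extremes),
       nrow(cohort$grades), nrow(dsi))

  # --- genotype QC ----------------------------------------------------
  Gf <- run_stage("qc", filter_variants(G, maf_min, mcf_max))
  kept <- run_stage("prune", do.call(ld_prune, c(list(Gf), prune_par)))
  write_tsv(data.frame(snp = Gf$variants$id[kept]),
            file.path(out_dir, "pruned_snps.tsv"), prov)
  K <- kinship(Gf)
  Qpc <- structure_covariates(subset_snps(Gf, kept), n_pcs)
  pi_tab <- windowed_pi(G)
  write_tsv(pi_tab, file.path(out_dir, "pi_windows.tsv"), prov)
  note("qc", sprintf("maf>=%.2f mcf<=%.2f", maf_min, mcf_max),
       ncol(G$dosages), ncol(Gf$dosages))
  note("prune", sprintf("window=%d step=%d r2=%.2f", prune_par$window,
                        prune_par$step, prune_par$r2_max),
       ncol(Gf$dosages), length(kept))

  # --- DSI mixed-model scan ------------------------------------------
  y <- dsi$dsi[match(G$sample_ids, dsi$accession)]
  fit <- run_stage("gwas", fit_null_lmm(y, K, Q = Qpc))
  assoc <- run_stage("gwas", wald_scan(Gf, fit))
  write_tsv(assoc, file.path(out_dir, "assoc_dsi.tsv"), prov)
  threshold <- bonferroni_threshold(alpha, length(kept))
  note("gwas", sprintf("pcs=%d threshold=%.3g", n_pcs, threshold),
       ncol(Gf$dosages), sum(assoc$p <= threshold))

  # --- loci -----------------------------------------------------------
  loci <- run_stage("loci", do.call(cluster_loci,
    c(list(assoc, threshold = threshold, trait = "DSI"), loci_par)))
  write_tsv(loci, file.path(out_dir, "loci_dsi.tsv"), prov)
  note("loci", sprintf("merge=%g span=%g min_snps=%d", loci_par$merge_bp,
                       loci_par$max_span_bp, loci_par$min_snps),
       sum(assoc$p <= threshold), nrow(loci))

  # --- metabolomics ---------------------------------------------------
  diff <- classes <- NULL
  if (isTRUE(with_met)) {
    Mall <- bind_conditions(cohort$metab_ck, cohort$metab_ds)
    write_metabolite_tsv(Mall, file.path(out_dir, "metabolites.tsv"))
    ck_i <- sample_idx(Mall, condition = "CK")
    ds_i <- sample_idx(Mall, condition = "DS")
    diff <- run_stage("metabo_diff", differential_call(Mall, ck_i, ds_i))
    write_tsv(diff, file.path(out_dir, "diff_ds_vs_ck.tsv"), prov)
    d_ck <- differential_call(cohort$metab_ck,
                              sample_idx(cohort$metab_ck, group = "S"),
                              sample_idx(cohort$metab_ck, group = "R"))
    d_ds <- differential_call(cohort$metab_ds,
                              sample_idx(cohort$metab_ds, group = "S"),
                              sample_idx(cohort$metab_ds, group = "R"))
    classes <- classify_inducible_constitutive(diff, d_ck, d_ds)
    write_tsv(classes, file.path(out_dir, "metabolite_classes.tsv"), prov)
    tree <- sample_nj_tree(Mall, file = file.path(out_dir, "samples.nwk"))
    note("metabo", "DS-vs-CK + R-vs-S + NJ tree", ncol(Mall$abundances),
         sum(diff$call != "ns"))
  } else {
    note("metabo", "skipped", NA, NA, status = "skipped: no metabolite input")
  }

  # --- haplotype test at the causal SNP ------------------------------
  hap <- tryCatch(
    genotype_class_test(G, cfg$causal_dsi_snp, y),
    error = function(e) NULL)
  if (!is.null(hap))
    write_tsv(hap$means, file.path(out_dir, "causal_snp_classes.tsv"), prov)
  note("haplotype", sprintf("snp=%d", cfg$causal_dsi_snp), nrow(G$dosages),
       if (is.null(hap)) 0L else nrow(hap$means))

  log_df <- do.call(rbind, log)
  write_tsv(log_df, file.path(out_dir, "run_log.tsv"), prov)
  invisible(list(cohort = cohort, assoc = assoc, loci = loci,
                 threshold = threshold, diff = diff, classes = classes,
                 fit = fit, log = log_df))
}
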