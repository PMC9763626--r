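#' Simulate structured diploid genotypes
#'
#' Draws genotypes under the Balding-Nichols model: an ancestral allele
#' frequency p0 ~ Uniform(maf_range) per SNP, and per-subpopulation
#' frequencies ~ Beta(p0(1-F)/F, (1-p0)(1-F)/F) with F = `fst` (F = 0 is
#' handled as the no-divergence limit, i.e. every subpopulation uses p0).
#' Local LD is induced by a first-order Markov copying process: within an
#' LD block each haplotype copies the previous SNP's allele with probability
#' `ld_copy_prob` and redraws from the subpopulation frequency otherwise.
#' Diploid dosages are the sum of two independent haplotypes; missing calls
#' are placed uniformly at `missing_rate`. Positions are strictly increasing
#' within each chromosome.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] with attributes `subpop` (per-accession
#'   subpopulation label) carried in `attr(,"subpop")`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_accessions
  m <- config$n_snps
  K <- config$n_subpops
  Fst <- config$fst

  subpop <- sample(rep_len(seq_len(K), n))
  hap_pop <- rep(subpop, each = 2L)          # 2n haplotypes

  p0 <- runif(m, config$maf_range[1], config$maf_range[2])
  # subpop frequencies: K x m
  if (Fst > 0) {
    a <- p0 * (1 - Fst) / Fst
    b <- (1 - p0) * (1 - Fst) / Fst
    pf <- matrix(rbeta(K * m, rep(a, each = K), rep(b, each = K)), nrow = K)
  } else {
    pf <- matrix(rep(p0, each = K), nrow = K)
  }

  per_chrom <- m %/% config$n_chromosomes
  counts <- rep(per_chrom, config$n_chromosomes)
  counts[config$n_chromosomes] <- m - per_chrom * (config$n_chromosomes - 1)
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes), "H"), counts)

  H <- matrix(0L, nrow = 2L * n, ncol = m)
  block <- config$ld_block_len
  copy <- config$ld_copy_prob
  offset <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    mc <- counts[ci]
    for (j in seq_len(mc)) {
      jj <- offset + j
      p_h <- pf[cbind(hap_pop, jj)]
      draw <- as.integer(runif(2L * n) < p_h)
      new_block <- ((j - 1L) %% block) == 0L
      if (new_block || j == 1L) {
        H[, jj] <- draw
      } else {
        keep <- runif(2L * n) < copy
        H[, jj] <- ifelse(keep, H[, jj - 1L], draw)
      }
    }
    offset <- offset + mc
  }

  dos <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
         H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  if (config$missing_rate > 0) {
    miss <- runif(n * m) < config$missing_rate
    dos[matrix(miss, nrow = n)] <- NA_integer_
  }

  pos <- integer(m)
  offset <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    mc <- counts[ci]
    pos[offset + seq_len(mc)] <-
      sort(sample.int(config$chrom_length_bp, mc))
    offset <- offset + mc
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  ids <- sprintf("ACC%03d", seq_len(n))
  G <- genotype_matrix(dos, variants, ids)
  attr(G, "subpop") <- subpop
  G
}

#' Simulate metabolite abundances under control and drought conditions
#'
#' Each feature is built on the log2 scale as
#' planted SNP effects + polygenic term + residual, with the planted effect
#' size chosen so its marginal variance fraction equals the target PVE, the
#' polygenic term drawn from MVN(0, h2 * K) with K the trace-normalised
#' realised kinship, and total variance 1. Drought-stress (DS) values share
#' the genetic components, draw an independent residual, and add the
#' feature's induction shift plus, for designated constitutive features,
#' group-specific offsets (resistant up, sensitive down). Raw abundances are
#' 2^(log2 value), hence strictly positive.
#'
#' @param config a [sim_config()].
#' @param G genotype matrix from [simulate_genotypes()] (or matching shape).
#' @param groups optional per-accession resistance class (`"R"`, `"S"`,
#'   `"intermediate"`); required for constitutive features to take effect.
#' @param h2 optional per-feature heritability vector overriding the Beta
#'   draw around `h2_mean`.
#' @return list with elements `ck` and `ds` ([metabolite_matrix()] objects)
#'   and `truth` (class `sim_truth`): causal map with true effect sizes,
#'   per-feature heritabilities, induction fold changes, constitutive
#'   feature indices and subpopulation labels.
#' @export
simulate_metabolites <- function(config, G, groups = NULL, h2 = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(G, "genotype_matrix"))
  set.seed(substream_seed(config$seed, "metabolites"))
  n <- nrow(G$dosages)
  p <- config$n_metabolites
  X <- impute_dosages(G)

  Kmat <- kinship(G)
  Ks <- Kmat * n / sum(diag(Kmat))       # mean diagonal 1
  L <- sample_stdnorm_sqrt(Ks)

  if (is.null(h2)) {
    conc <- 10
    h2 <- rbeta(p, config$h2_mean * conc, (1 - config$h2_mean) * conc)
  } else {
    stopifnot(length(h2) == p, all(h2 >= 0 & h2 <= 1))
  }

  pq <- config$planted_qtls
  qtl_pve <- numeric(p)
  if (nrow(pq)) {
    agg <- tapply(pq$pve, pq$metabolite, sum)
    qtl_pve[as.integer(names(agg))] <- agg
  }
  if (any(qtl_pve >= 1))
    stop_named("invalid_argument", "total planted PVE per metabolite must be < 1")
  # background heritability scaled into the non-QTL variance share so the
  # components always sum to 1
  var_g <- (1 - qtl_pve) * h2
  var_e <- (1 - qtl_pve) * (1 - h2)
  if (any(qtl_pve + var_g > 1 + 1e-12))
    stop_named("invalid_argument", "planted PVE plus background h2 exceeds 1")

  # induction + constitutive feature assignment, disjoint from each other
  special <- sample.int(p, config$n_inducible + config$n_constitutive)
  inducible <- if (config$n_inducible) special[seq_len(config$n_inducible)] else integer(0)
  constitutive <- setdiff(special, inducible)
  ind_fc <- numeric(p)
  if (length(inducible)) {
    mag <- runif(length(inducible), config$induction_log2fc_range[1],
                 config$induction_log2fc_range[2])
    sgn <- sample(c(-1, 1), length(inducible), replace = TRUE)
    ind_fc[inducible] <- mag * sgn
  }

  mu <- runif(p, 10, 20)
  Zg <- L %*% matrix(rnorm(n * p), n, p)   # polygenic, unit variance columns
  Eck <- matrix(rnorm(n * p), n, p)
  Eds <- matrix(rnorm(n * p), n, p)

  beta_map <- NULL
  Yq <- matrix(0, n, p)
  if (nrow(pq)) {
    xs <- X[, pq$snp, drop = FALSE]
    xs <- scale(xs, center = TRUE, scale = FALSE)
    vx <- apply(xs, 2, function(v) mean(v^2))
    beta <- sqrt(pq$pve / pmax(vx, 1e-12))
    for (i in seq_len(nrow(pq)))
      Yq[, pq$metabolite[i]] <- Yq[, pq$metabolite[i]] + beta[i] * xs[, i]
    beta_map <- data.frame(snp = pq$snp, metabolite = pq$metabolite,
                           true_beta = beta, pve = pq$pve)
  }

  base <- sweep(Yq, 2, rep(1, p), "*") +
    sweep(Zg, 2, sqrt(var_g), "*")
  lck <- sweep(base + sweep(Eck, 2, sqrt(var_e), "*"), 2, mu, "+")
  lds <- sweep(base + sweep(Eds, 2, sqrt(var_e), "*"), 2, mu, "+")
  lds <- sweep(lds, 2, ind_fc, "+")

  grp <- groups %||% rep("intermediate", n)
  if (length(constitutive)) {
    off <- (grp == "R") * (config$constitutive_log2diff / 2) -
           (grp == "S") * (config$constitutive_log2diff / 2)
    lck[, constitutive] <- lck[, constitutive] + off
    lds[, constitutive] <- lds[, constitutive] + off
  }

  feat <- data.frame(id = sprintf("M%04d", seq_len(p)),
                     stringsAsFactors = FALSE)
  mk <- function(lmat, cond) {
    ab <- 2^lmat
    rownames(ab) <- paste0(G$sample_ids, "_", cond)
    colnames(ab) <- feat$id
    metabolite_matrix(ab,
                      sample_meta = data.frame(
                        sample = rownames(ab),
                        accession = G$sample_ids,
                        condition = cond,
                        group = grp,
                        stringsAsFactors = FALSE),
                      feature_meta = feat)
  }
  truth <- structure(list(
    causal_map = beta_map,
    subpop_labels = attr(G, "subpop"),
    true_h2 = var_g / (var_g + var_e),   # heritability of the non-QTL part
    true_marginal_h2 = qtl_pve + var_g,
    true_induction_fc = 2^ind_fc,
    inducible_features = sort(inducible),
    constitutive_features = sort(constitutive)
  ), class = "sim_truth")
  list(ck = mk(lck, "CK"), ds = mk(lds, "DS"), truth = truth)
}

#' Simulate wilting observations driven by a causal SNP
#'
#' A per-accession liability is the causal SNP effect (variance share
#' `dsi_snp_pve`) plus standard normal noise. Each replicate adds its own
#' liability noise; the latent wilting rate at 72/96/120 h is a logistic
#' function of liability plus the (non-decreasing) timepoint shift, so the
#' expected rate is monotone in both liability and time. Counts of wilted
#' leaves are binomial draws out of `total_leaves`, and grades follow the
#' standard 0-4 wilting-rate bins.
#'
#' @param config a [sim_config()].
#' @param G genotype matrix containing `config$causal_dsi_snp`.
#' @return A grade table data.frame (accession, replicate, timepoint_h,
#'   total_leaves, wilted_leaves, wilting_rate, grade) with the per-accession
#'   liability attached as `attr(, "liability")`.
#' @export
simulate_wilting <- function(config, G) {
  stopifnot(inherits(config, "sim_config"), inherits(G, "genotype_matrix"))
  if (config$causal_dsi_snp > ncol(G$dosages))
    stop_named("invalid_argument", "causal_dsi_snp not present in G")
  set.seed(substream_seed(config$seed, "wilting"))
  n <- nrow(G$dosages)
  X <- impute_dosages(G)
  x <- X[, config$causal_dsi_snp]
  xc <- x - mean(x)
  pve <- config$dsi_snp_pve
  beta <- if (pve > 0) sqrt(pve / max(mean(xc^2), 1e-12)) else 0
  liability <- beta * xc + rnorm(n, sd = sqrt(1 - pve))

  reps <- seq_len(config$n_replicates)
  tps <- c(72L, 96L, 120L)
  out <- expand.grid(accession = G$sample_ids, replicate = reps,
                     timepoint_h = tps, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$replicate, out$timepoint_h), ]
  rownames(out) <- NULL
  acc_i <- match(out$accession, G$sample_ids)
  rep_noise <- matrix(rnorm(n * config$n_replicates, sd = config$replicate_sd),
                      n, config$n_replicates)
  shift <- config$timepoint_shift[match(out$timepoint_h, tps)]
  lat <- config$rate_slope *
    (liability[acc_i] + rep_noise[cbind(acc_i, out$replicate)]) + shift
  rate_latent <- stats::plogis(lat)
  out$total_leaves <- config$total_leaves
  out$wilted_leaves <- stats::rbinom(nrow(out), config$total_leaves, rate_latent)
  if (config$na_rate > 0) {
    na_idx <- runif(nrow(out)) < config$na_rate
    out$wilted_leaves[na_idx] <- NA_integer_
  }
  out$wilting_rate <- out$wilted_leaves / out$total_leaves
  out$grade <- wilting_rate_to_grade(out$wilting_rate)
  attr(out, "liability") <- liability
  out
}

#' Simulate a full drought cohort with ground truth
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_wilting()],
#' DSI scoring and extreme-group classification, then
#' [simulate_metabolites()] with the realised R/S/intermediate groups, so
#' that constitutive R/S-differential features are planted against the same
#' groups the downstream analyses will use.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `grades`, `dsi` (classified DSI table),
#'   `metab_ck`, `metab_ds` and `truth`.
#' @export
simulate_cohort <- function(config) {
  G <- simulate_genotypes(config)
  grades <- simulate_wilting(config, G)
  dsi <- compute_dsi(grades)
  dsi <- classify_extremes(dsi, k = config$k_extremes)
  groups <- dsi$resistance_class[match(G$sample_ids, dsi$accession)]
  met <- simulate_metabolites(config, G, groups = groups)
  truth <- met$truth
  truth$true_grades_liability <- attr(grades, "liability")
  truth$causal_dsi_snp <- config$causal_dsi_snp
  list(genotypes = G, grades = grades, dsi = dsi,
       metab_ck = met$ck, metab_ds = met$ds, truth = truth)
}
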