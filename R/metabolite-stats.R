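# Metabolomics statistics: transforms, PLS-DA/VIP, differential calling,
# the four-group fold-change framework, inducible/constitutive
# classification, correlation structure and sample clustering.

as_abundance <- function(M) {
  if (inherits(M, "metabolite_matrix")) M$abundances else as.matrix(M)
}

#' Log2 transform of raw metabolite abundances
#'
#' @param M a [metabolite_matrix()] or positive numeric matrix.
#' @return numeric matrix of log2 values (samples x features).
#' @export
log2_transform <- function(M) {
  A <- as_abundance(M)
  if (any(A <= 0)) stop_named("invalid_abundance", "log2 requires values > 0")
  log2(A)
}

#' Per-feature min-max normalization
#'
#' Maps each feature to [0, 1] via (x - min) / (max - min); constant
#' features map to all zeros.
#'
#' @param M a [metabolite_matrix()] or numeric matrix.
#' @return numeric matrix on [0, 1].
#' @export
minmax_normalize <- function(M) {
  A <- as_abundance(M)
  apply(A, 2, function(v) {
    rng <- range(v)
    if (rng[2] - rng[1] <= 0) return(rep(0, length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  })
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a NIPALS partial-least-squares model against a centered two-class
#' dummy response (+1/-1) on autoscaled features and returns per-feature
#' VIP scores: VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a) with
#' SSY_a the response variance captured by component a and w_a the (unit
#' norm) weight vector, so that sum_j VIP_j^2 = p exactly.
#'
#' @param X numeric matrix (samples x features), typically log2 abundances.
#' @param classes two-level factor/vector of class labels.
#' @param n_components number of PLS components (default 2, capped at the
#'   available rank).
#' @param autoscale center and unit-variance scale features (default TRUE).
#' @return numeric vector of VIP scores, one per feature.
#' @export
plsda_vip <- function(X, classes, n_components = 2, autoscale = TRUE) {
  X <- as.matrix(X)
  cl <- as.factor(classes)
  if (nlevels(cl) != 2)
    stop_named("invalid_classes", "PLS-DA needs exactly two classes, got %d",
               nlevels(cl))
  if (any(table(cl) < 2))
    stop_named("invalid_classes", "each class needs >= 2 samples")
  p <- ncol(X)
  y <- ifelse(cl == levels(cl)[1], 1, -1)
  y <- y - mean(y)
  if (autoscale) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- scale(X, center = TRUE, scale = sds)
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  A <- min(n_components, nrow(X) - 1L, p)
  W <- matrix(0, p, A)
  ssy <- numeric(A)
  used <- 0L
  for (a in seq_len(A)) {
    wv <- drop(crossprod(X, y))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- drop(X %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(X, tv)) / tt
    qv <- sum(y * tv) / tt
    X <- X - tcrossprod(tv, pl)
    y <- y - qv * tv
    W[, a] <- wv
    ssy[a] <- qv^2 * tt
    used <- a
  }
  if (used == 0L) return(rep(0, p) * NA_real_)
  W <- W[, seq_len(used), drop = FALSE]
  ssy <- ssy[seq_len(used)]
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)
  vip
}

# vectorized two-sample t-test on columns; pooled (Student) by default
.col_ttest <- function(A, B, welch = FALSE, paired = FALSE) {
  na <- nrow(A); nb <- nrow(B)
  if (paired) {
    stopifnot(na == nb)
    D <- A - B
    mu <- colMeans(D); s2 <- apply(D, 2, stats::var)
    se <- sqrt(s2 / na); df <- na - 1
    tstat <- mu / se
  } else {
    ma <- colMeans(A); mb <- colMeans(B)
    va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
    if (welch) {
      se2 <- va / na + vb / nb
      tstat <- (mb - ma) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    } else {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      tstat <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    }
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate features: zero variance everywhere and equal means -> p = 1
  p[!is.finite(tstat) & abs(colMeans(B) - colMeans(A)) < 1e-300] <- 1
  p[is.nan(p)] <- 1
  p
}

#' Differential metabolite calling between two sample groups
#'
#' A feature is called `up` when VIP > `vip_min`, fold change (group b over
#' group a, on raw group means) >= `fc_up` and adjusted t-test P < `p_max`;
#' `down` when VIP > `vip_min`, fold change <= `fc_down` and adjusted P <
#' `p_max`; `ns` otherwise. Tests run on log2 values with a pooled-variance
#' (classic Student) t by default; P-values are Benjamini-Hochberg adjusted
#' across features.
#'
#' @param M a [metabolite_matrix()].
#' @param group_a,group_b row indices (or logical masks) of the two groups;
#'   group a is the reference/denominator.
#' @param vip_min VIP threshold (default 1.0).
#' @param fc_up,fc_down fold-change thresholds (default 1.5 and 0.67).
#' @param p_max adjusted P threshold (default 0.05).
#' @param welch use Welch instead of pooled-variance t.
#' @param paired paired t-test (samples matched by row order).
#' @param p_adjust multiple-testing method (default `"BH"`).
#' @return data.frame of class `diff_result`: feature, fc, log2fc, vip,
#'   p_raw, p_adj, call.
#' @export
differential_call <- function(M, group_a, group_b, vip_min = 1,
                              fc_up = 1.5, fc_down = 0.67, p_max = 0.05,
                              welch = FALSE, paired = FALSE,
                              p_adjust = "BH") {
  A <- as_abundance(M)
  ga <- if (is.logical(group_a)) which(group_a) else group_a
  gb <- if (is.logical(group_b)) which(group_b) else group_b
  if (length(ga) < 3 || length(gb) < 3)
    stop_named("invalid_groups", "both groups need >= 3 samples")
  L <- log2(A)
  fc <- colMeans(A[gb, , drop = FALSE]) / colMeans(A[ga, , drop = FALSE])
  p_raw <- .col_ttest(L[ga, , drop = FALSE], L[gb, , drop = FALSE],
                      welch = welch, paired = paired)
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  vip <- plsda_vip(L[c(ga, gb), , drop = FALSE],
                   rep(c("a", "b"), c(length(ga), length(gb))))
  call <- rep("ns", ncol(A))
  sig <- !is.na(vip) & vip > vip_min & p_adj < p_max
  call[sig & fc >= fc_up] <- "up"
  call[sig & fc <= fc_down] <- "down"
  out <- data.frame(
    feature = colnames(A) %||% sprintf("M%04d", seq_len(ncol(A))),
    fc = fc, log2fc = log2(fc), vip = as.numeric(vip),
    p_raw = p_raw, p_adj = p_adj, call = call,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Four-group fold-change framework
#'
#' Per-feature group-mean fold changes for the four contrasts
#' R_DS/R_CK and S_DS/S_CK (drought induction within the resistant and
#' sensitive groups) and R_CK/S_CK and R_DS/S_DS (constitutive
#' resistant-vs-sensitive differences within each condition), plus
#' rank-sum (Wilcoxon) tests comparing the |log2 FC| distributions between
#' every pair of contrasts.
#'
#' @param M a [metabolite_matrix()] containing both conditions and R/S
#'   groups.
#' @return list with `fc` (features x 4 contrasts data.frame) and `wilcox`
#'   (pairwise contrast comparisons of |log2 FC|).
#' @export
four_group_fc <- function(M) {
  stopifnot(inherits(M, "metabolite_matrix"))
  cells <- list(R_CK = c("R", "CK"), R_DS = c("R", "DS"),
                S_CK = c("S", "CK"), S_DS = c("S", "DS"))
  idx <- lapply(cells, function(gc) sample_idx(M, condition = gc[2], group = gc[1]))
  empty <- names(idx)[vapply(idx, length, 0L) == 0]
  if (length(empty))
    stop_named("missing_cell", "no samples in cell(s): %s",
               paste(empty, collapse = ", "))
  A <- M$abundances
  mns <- vapply(idx, function(i) colMeans(A[i, , drop = FALSE]),
                numeric(ncol(A)))
  fc <- data.frame(
    feature = M$feature_meta$id,
    R_DS_over_R_CK = mns[, "R_DS"] / mns[, "R_CK"],
    S_DS_over_S_CK = mns[, "S_DS"] / mns[, "S_CK"],
    R_CK_over_S_CK = mns[, "R_CK"] / mns[, "S_CK"],
    R_DS_over_S_DS = mns[, "R_DS"] / mns[, "S_DS"],
    stringsAsFactors = FALSE)
  rownames(fc) <- NULL
  contrasts <- names(fc)[-1]
  pairs <- utils::combn(contrasts, 2)
  wres <- apply(pairs, 2, function(pr) {
    a <- abs(log2(fc[[pr[1]]])); b <- abs(log2(fc[[pr[2]]]))
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(a, b)$p.value),
      error = function(e) NA_real_)
    if (is.nan(p)) p <- NA_real_
    p
  })
  wilcox <- data.frame(contrast_a = pairs[1, ], contrast_b = pairs[2, ],
                       p = wres, stringsAsFactors = FALSE)
  list(fc = fc, wilcox = wilcox)
}

#' Classify features as drought-inducible or constitutively differential
#'
#' Combines three differential-call sets: the cohort-wide DS-vs-CK calls
#' (`diff_all`) and the resistant-vs-sensitive calls within each condition
#' (`diff_rs_ck`, `diff_rs_ds`). A feature is `inducible` when called in
#' `diff_all` only; `constitutive_differential` when called in the same
#' direction in both R-vs-S sets but not in `diff_all`; `both` when called
#' in `diff_all` and in both R-vs-S sets; `neither` otherwise. The labels
#' partition the features.
#'
#' @param diff_all,diff_rs_ck,diff_rs_ds `diff_result` tables over the same
#'   features.
#' @return data.frame: feature, label.
#' @export
classify_inducible_constitutive <- function(diff_all, diff_rs_ck, diff_rs_ds) {
  stopifnot(identical(diff_all$feature, diff_rs_ck$feature),
            identical(diff_all$feature, diff_rs_ds$feature))
  called_all <- diff_all$call != "ns"
  const <- diff_rs_ck$call != "ns" & diff_rs_ck$call == diff_rs_ds$call
  label <- rep("neither", nrow(diff_all))
  label[called_all & !const] <- "inducible"
  label[!called_all & const] <- "constitutive_differential"
  label[called_all & const] <- "both"
  data.frame(feature = diff_all$feature, label = label,
             stringsAsFactors = FALSE)
}

#' Feature-feature Spearman correlation matrix
#'
#' Tie-corrected Spearman rank correlations between all feature pairs, with
#' t-approximation P-values Benjamini-Hochberg adjusted over the upper
#' triangle. Constant features yield NA rows/columns.
#'
#' @param M a [metabolite_matrix()] or numeric matrix (samples x features).
#' @return list with matrices `rho`, `p_raw`, `p_adj`.
#' @export
spearman_matrix <- function(M) {
  A <- as_abundance(M)
  n <- nrow(A)
  if (n < 5) stop_named("invalid_argument", "need >= 5 samples")
  sds <- apply(A, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(A, method = "spearman"))
  rho[sds == 0, ] <- NA; rho[, sds == 0] <- NA
  diag(rho)[sds > 0] <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA
  up <- upper.tri(p)
  padj <- p
  padj[up] <- stats::p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(rho = rho, p_raw = p, p_adj = padj)
}

#' Neighbor-joining tree of samples on simple matching distance
#'
#' Features are binarized at their cohort median (>= median becomes 1); the
#' simple matching distance between two samples is the fraction of features
#' in different states. The tree is standard neighbor joining with negative
#' branch lengths clamped to zero.
#'
#' @param M a [metabolite_matrix()] or numeric matrix.
#' @param file optional path; when given the tree is also written as Newick.
#' @param dist optional precomputed sample-distance matrix overriding the
#'   binarize-and-match step (e.g. for joining an externally defined
#'   distance).
#' @return An [ape::nj()] `phylo` object.
#' @export
sample_nj_tree <- function(M, file = NULL, dist = NULL) {
  A <- as_abundance(M)
  if (nrow(A) < 4) stop_named("invalid_argument", "need >= 4 samples")
  if (is.null(dist)) {
    med <- apply(A, 2, stats::median)
    B <- sweep(A, 2, med, ">=") * 1
    D <- simple_matching_distance(B)
  } else {
    D <- as.matrix(dist)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(file)) ape::write.tree(tr, file = file)
  tr
}

#' Simple matching distance between rows of a binary matrix
#'
#' @param B binary matrix (samples x features).
#' @return symmetric distance matrix: fraction of mismatching features.
#' @export
simple_matching_distance <- function(B) {
  B <- as.matrix(B) * 1
  m <- ncol(B)
  # mismatches = x(1-y)' + (1-x)y'
  S <- tcrossprod(B) + tcrossprod(1 - B)
  D <- (m - S) / m
  rownames(D) <- colnames(D) <- rownames(B)
  D
}

#' Principal component scores of metabolite profiles
#'
#' PCA on log2-transformed, feature-centered abundances.
#'
#' @param M a [metabolite_matrix()] or positive matrix.
#' @param n_components number of components to return (default 2).
#' @return list with `scores` (samples x components) and `var_explained`
#'   (fractions, all components).
#' @export
pca_scores <- function(M, n_components = 2) {
  L <- log2_transform(M)
  if (nrow(L) < 3) stop_named("invalid_argument", "need >= 3 samples")
  pc <- stats::prcomp(L, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE], var_explained = ve)
}
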