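# Linear mixed-model association scan.
#
# Model: y = X b + g + e with g ~ N(0, sigma_g2 K), e ~ N(0, sigma_e2 I).
# A single eigendecomposition of K rotates the model to independent
# observations; the variance ratio delta = sigma_e2 / sigma_g2 is profiled
# out of the (restricted) likelihood and found by a deterministic log-grid
# scan plus local refinement. K is rescaled internally to mean diagonal 1 so
# that pseudo-heritability sigma_g2 / (sigma_g2 + sigma_e2) is on the
# marginal-variance scale.

# restricted / full log-likelihood at a given variance ratio, in the rotated
# space (D = eigenvalues of K, ys/Xs = rotated phenotype/covariates)
.lmm_loglik <- function(delta, D, ys, Xs, reml = TRUE) {
  w <- 1 / (D + delta)
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  beta <- backsolve(R, forwardsolve(t(R), XtWy))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  n <- length(ys); q <- ncol(Xs)
  if (reml) {
    sigma2 <- rss / (n - q)
    ldXtX <- determinant(crossprod(Xs), logarithm = TRUE)$modulus
    -0.5 * ((n - q) * log(2 * pi * sigma2) + (n - q) -
              sum(log(w)) + 2 * sum(log(diag(R))) - as.numeric(ldXtX))
  } else {
    sigma2 <- rss / n
    -0.5 * (n * log(2 * pi * sigma2) + n - sum(log(w)))
  }
}

.optimize_delta <- function(D, ys, Xs, reml = TRUE,
                            lower = 1e-5, upper = 1e5, n_grid = 100) {
  lg <- seq(log(lower), log(upper), length.out = n_grid)
  ll <- vapply(lg, function(l) .lmm_loglik(exp(l), D, ys, Xs, reml), 0)
  i <- which.max(ll)
  lo <- lg[max(1L, i - 1L)]; hi <- lg[min(length(lg), i + 1L)]
  opt <- stats::optimize(function(l) .lmm_loglik(exp(l), D, ys, Xs, reml),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  list(delta = exp(opt$maximum), loglik = opt$objective)
}

# build the covariate matrix: always an intercept, plus user columns
.build_covar <- function(n, Q) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    stopifnot(nrow(Q) == n)
    # drop a user-supplied intercept duplicate
    keep <- apply(Q, 2, function(v) stats::sd(v) > 0)
    X <- cbind(X, Q[, keep, drop = FALSE])
  }
  if (qr(X)$rank < ncol(X))
    stop_named("rank_deficient", "covariate matrix is rank deficient")
  X
}

#' Fit the null linear mixed model
#'
#' Estimates the variance components of y = Q b + g + e with
#' g ~ N(0, sigma_g2 K) and e ~ N(0, sigma_e2 I) by REML (default) or ML.
#' K is eigendecomposed once (after rescaling to mean diagonal 1) and the
#' variance ratio is profiled out; optimization is a deterministic 100-point
#' log-grid scan over [1e-5, 1e5] followed by local refinement.
#'
#' @param y numeric phenotype vector (log2 scale for metabolite traits).
#' @param K kinship matrix from [kinship()] (any symmetric PSD relatedness
#'   matrix works).
#' @param Q optional covariate matrix (structure PCs etc.); an intercept is
#'   always added.
#' @param reml use restricted maximum likelihood (default) or ML.
#' @return An object of class `lmm_fit` with elements `sigma_g2`,
#'   `sigma_e2`, `delta`, `pseudo_h2`, `loglik`, `eigen_cache` (values,
#'   vectors, scale), plus the rotated data reused by [wald_scan()].
#' @export
fit_null_lmm <- function(y, K, Q = NULL, reml = TRUE) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop_named("invalid_phenotype", "y must be finite")
  n <- length(y)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  scale_k <- n / sum(diag(K))
  Ks <- K * scale_k
  eg <- eigen(Ks, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  X <- .build_covar(n, Q)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  opt <- .optimize_delta(D, ys, Xs, reml = reml)
  delta <- opt$delta
  w <- 1 / (D + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  sigma_g2 <- rss / (if (reml) n - ncol(X) else n)
  structure(list(
    sigma_g2 = sigma_g2,
    sigma_e2 = delta * sigma_g2,
    delta = delta,
    pseudo_h2 = 1 / (1 + delta),
    loglik = opt$loglik,
    reml = reml,
    beta_null = drop(beta),
    eigen_cache = list(values = D, vectors = U, scale = scale_k),
    y = y, X = X, ys = drop(ys), Xs = Xs
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit (%s): sigma_g2 = %.4g, sigma_e2 = %.4g, pseudo-h2 = %.3f\n",
              if (x$reml) "REML" else "ML", x$sigma_g2, x$sigma_e2, x$pseudo_h2))
  cat(sprintf("  delta = %.4g, loglik = %.3f, n = %d, covariates = %d\n",
              x$delta, x$loglik, length(x$y), ncol(x$X)))
  invisible(x)
}

#' Genome-wide association scan by generalized least squares
#'
#' Tests each SNP in the rotated mixed-model space. In the default
#' approximate mode the null model's variance ratio is reused for every SNP
#' (the standard fast approximation); `exact = TRUE` re-optimizes the ratio
#' per SNP. Missing dosages are mean-imputed. The Wald statistic is referred
#' to an F(1, n - q - 1) distribution, which reduces exactly to the ordinary
#' regression test when K is the identity. Monomorphic SNPs are flagged and
#' reported with beta 0 and p 1.
#'
#' @param G a [genotype_matrix()].
#' @param fit an `lmm_fit` from [fit_null_lmm()] on the same samples.
#' @param exact re-optimize the variance ratio per SNP.
#' @return data.frame of class `assoc_result`: snp, chrom, pos, ref, alt,
#'   maf, beta, se, p, pve, monomorphic.
#' @export
wald_scan <- function(G, fit, exact = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(fit, "lmm_fit"))
  n <- length(fit$y)
  if (nrow(G$dosages) != n)
    stop_named("invalid_argument", "G and fit have different sample counts")
  U <- fit$eigen_cache$vectors
  D <- fit$eigen_cache$values
  Xs <- fit$Xs; ys <- fit$ys
  q <- ncol(Xs)
  Gm <- impute_dosages(G)
  vx <- apply(Gm, 2, function(v) mean((v - mean(v))^2))
  mono <- vx < 1e-12
  vy <- mean((fit$y - mean(fit$y))^2)
  Gs <- crossprod(U, Gm)

  m <- ncol(Gm)
  beta <- numeric(m); se <- rep(NA_real_, m); pval <- rep(1, m)
  if (!exact) {
    w <- 1 / (D + fit$delta)
    sw <- sqrt(w)
    yt <- sw * ys
    Xt <- Xs * sw
    Gt <- Gs * sw
    qrX <- qr(Xt)
    ry <- qr.resid(qrX, yt)
    RG <- qr.resid(qrX, Gt)
    gss <- colSums(RG^2)
    gy <- colSums(RG * ry)
    ok <- !mono & gss > 1e-12
    df <- n - q - 1
    b <- gy[ok] / gss[ok]
    rss <- sum(ry^2) - gy[ok]^2 / gss[ok]
    s2 <- rss / df
    beta[ok] <- b
    se[ok] <- sqrt(s2 / gss[ok])
    fstat <- b^2 / (s2 / gss[ok])
    pval[ok] <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  } else {
    df <- n - q - 1
    for (j in seq_len(m)) {
      if (mono[j]) next
      Xj <- cbind(Xs, Gs[, j])
      opt <- .optimize_delta(D, ys, Xj, reml = fit$reml)
      w <- 1 / (D + opt$delta)
      XtWX <- crossprod(Xj, Xj * w)
      bb <- solve(XtWX, crossprod(Xj, ys * w))
      r <- ys - Xj %*% bb
      s2 <- sum(w * r^2) / df
      covb <- solve(XtWX) * s2
      beta[j] <- bb[q + 1]
      se[j] <- sqrt(covb[q + 1, q + 1])
      pval[j] <- stats::pf((beta[j] / se[j])^2, 1, df, lower.tail = FALSE)
    }
  }
  pve <- pmin(pmax(beta^2 * vx / vy, 0), 1)
  out <- data.frame(
    snp = G$variants$id,
    chrom = G$variants$chrom,
    pos = G$variants$pos,
    ref = G$variants$ref,
    alt = G$variants$alt,
    maf = snp_maf(G),
    beta = beta, se = se, p = pval, pve = pve,
    monomorphic = mono,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Phenotypic variance explained by a single SNP
#'
#' The conventional marginal definition PVE = beta^2 Var(x) / Var(y),
#' clipped to [0, 1].
#'
#' @param beta estimated additive effect of the SNP.
#' @param x dosage vector (missing values mean-imputed).
#' @param y phenotype vector.
#' @return fraction in [0, 1].
#' @export
snp_pve <- function(beta, x, y) {
  x <- as.numeric(x)
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  vy <- mean((y - mean(y))^2)
  if (vy <= 0) stop_named("invalid_argument", "Var(y) must be > 0")
  vx <- mean((x - mean(x))^2)
  min(max(beta^2 * vx / vy, 0), 1)
}

#' Bonferroni-style significance threshold from an effective SNP count
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_effective effective number of independent tests (e.g. the size
#'   of an LD-pruned SNP set).
#' @return P-value threshold alpha / n_effective.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_effective) {
  check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  n_effective <- check_count(n_effective, "n_effective")
  alpha / n_effective
}

#' Genomic inflation factor
#'
#' lambda_GC = median observed 1-df chi-square statistic divided by the
#' median of the chi-square(1) distribution (0.4549).
#'
#' @param p vector of P-values, or an `assoc_result`.
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p) {
  if (is.data.frame(p)) p <- p$p
  p <- p[!is.na(p)]
  if (length(p) < 100)
    warning("lambda_GC is unstable with fewer than 100 tests")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
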