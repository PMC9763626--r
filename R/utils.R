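# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(code, "qkmgwas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop_named("invalid_argument", "'%s' must be in %s%g, %g%s, got %s",
                      name, if (lo_open) "(" else "[", lo, hi,
                      if (hi_open) ")" else "]", format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) stop_named("invalid_argument", "'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# Derive a reproducible sub-stream seed so that adding a stage never shifts
# another stage's random numbers.  Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  offsets <- c(genotypes = 11L, wilting = 29L, metabolites = 47L,
               qc = 61L, gwas = 83L, metabo = 97L, haplotype = 113L)
  off <- offsets[[stage]] %||% 127L
  as.integer((as.numeric(seed) * 1000 + off) %% 2147483647)
}

sample_stdnorm_sqrt <- function(K) {
  # symmetric square root via eigendecomposition; small negative eigenvalues
  # from numerical error are clamped
  e <- eigen(K, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}
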