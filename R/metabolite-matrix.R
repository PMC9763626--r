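#' Construct a metabolite abundance matrix
#'
#' Couples a samples x features matrix of strictly positive raw abundances
#' with per-sample metadata (accession, condition CK/DS, resistance group)
#' and per-feature metadata.
#'
#' @param abundances numeric matrix, samples in rows, features in columns,
#'   all entries > 0.
#' @param sample_meta data.frame with one row per sample; must contain
#'   `accession` and `condition` (`"CK"` or `"DS"`); `group` (R/S/
#'   intermediate) is optional and defaults to intermediate.
#' @param feature_meta optional data.frame with an `id` column.
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(abundances, sample_meta, feature_meta = NULL) {
  abundances <- as.matrix(abundances)
  if (any(!is.finite(abundances)) || any(abundances <= 0))
    stop_named("invalid_abundance", "abundances must be finite and > 0")
  stopifnot(is.data.frame(sample_meta),
            nrow(sample_meta) == nrow(abundances),
            all(c("accession", "condition") %in% names(sample_meta)))
  if (!all(sample_meta$condition %in% c("CK", "DS")))
    stop_named("invalid_condition", "condition must be 'CK' or 'DS'")
  if (is.null(sample_meta$group)) sample_meta$group <- "intermediate"
  if (is.null(feature_meta))
    feature_meta <- data.frame(
      id = colnames(abundances) %||% sprintf("M%04d", seq_len(ncol(abundances))),
      stringsAsFactors = FALSE)
  stopifnot(nrow(feature_meta) == ncol(abundances))
  colnames(abundances) <- feature_meta$id
  structure(list(abundances = abundances, sample_meta = sample_meta,
                 feature_meta = feature_meta),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d samples x %d features\n",
              nrow(x$abundances), ncol(x$abundances)))
  print(table(condition = x$sample_meta$condition, group = x$sample_meta$group))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$abundances)

#' Stack control and drought metabolite matrices into one object
#'
#' @param ck,ds `metabolite_matrix` objects sharing the same features.
#' @return A single `metabolite_matrix` with both conditions.
#' @export
bind_conditions <- function(ck, ds) {
  stopifnot(inherits(ck, "metabolite_matrix"), inherits(ds, "metabolite_matrix"),
            identical(ck$feature_meta$id, ds$feature_meta$id))
  metabolite_matrix(rbind(ck$abundances, ds$abundances),
                    rbind(ck$sample_meta, ds$sample_meta),
                    ck$feature_meta)
}

#' Row indices of samples in a (condition, group) cell
#'
#' @param M a [metabolite_matrix()].
#' @param condition optional condition filter (`"CK"`/`"DS"`).
#' @param group optional resistance-group filter (`"R"`/`"S"`/
#'   `"intermediate"`).
#' @return integer vector of matching sample rows.
#' @export
sample_idx <- function(M, condition = NULL, group = NULL) {
  keep <- rep(TRUE, nrow(M$abundances))
  if (!is.null(condition)) keep <- keep & M$sample_meta$condition %in% condition
  if (!is.null(group)) keep <- keep & M$sample_meta$group %in% group
  which(keep)
}
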