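#' Convert wilting rates to ordinal drought-resistance grades
#'
#' Grades bin the fraction of wilted leaves: 0 for a rate of exactly 0,
#' 1 for (0, 0.25], 2 for (0.25, 0.5], 3 for (0.5, 0.75] and 4 for
#' (0.75, 1]. Bin edges are half-open on the left so that every rate maps
#' to exactly one grade; grade 0 is the most resistant, grade 4 the most
#' sensitive. `NA` rates pass through as `NA` grades.
#'
#' @param rate numeric vector of wilting rates in [0, 1] (or NA).
#' @return integer vector of grades 0-4 (or NA).
#' @export
wilting_rate_to_grade <- function(rate) {
  rate <- as.numeric(rate)
  ok <- is.na(rate) | (rate >= 0 & rate <= 1)
  if (!all(ok)) stop_named("invalid_rate", "wilting rate outside [0, 1]")
  g <- rep(NA_integer_, length(rate))
  nz <- !is.na(rate)
  g[nz] <- as.integer(cut(rate[nz], breaks = c(-Inf, 0, 0.25, 0.5, 0.75, 1),
                          labels = FALSE)) - 1L
  g
}

#' Compute the drought-sensitivity index (DSI)
#'
#' For each accession, grades are averaged over replicates within each of
#' the three timepoints (72, 96, 120 h), and the DSI is the mean of the
#' three timepoint means: DSI = (Grade72h + Grade96h + Grade120h) / 3.
#' A timepoint with no non-NA replicate makes the accession's DSI `NA`
#' (mirroring the exclusion of low-germination replicates); partial
#' replicate NA is tolerated.
#'
#' @param grades grade table with columns `accession`, `replicate`,
#'   `timepoint_h` (72/96/120) and `grade` (or `wilting_rate` from which the
#'   grade is derived).
#' @return data.frame of class `dsi_table`: accession, the three per-
#'   timepoint mean grades, and `dsi`.
#' @export
compute_dsi <- function(grades) {
  stopifnot(is.data.frame(grades),
            all(c("accession", "timepoint_h") %in% names(grades)))
  if (is.null(grades$grade)) {
    if (is.null(grades$wilting_rate))
      stop_named("invalid_argument", "need a 'grade' or 'wilting_rate' column")
    grades$grade <- wilting_rate_to_grade(grades$wilting_rate)
  }
  tps <- c(72, 96, 120)
  bad <- setdiff(unique(grades$timepoint_h), tps)
  if (length(bad))
    stop_named("unknown_timepoint", "unknown timepoint(s): %s",
               paste(bad, collapse = ", "))
  acc <- sort(unique(grades$accession))
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  tp_means <- vapply(tps, function(tp) {
    sub <- grades[grades$timepoint_h == tp, ]
    vapply(acc, function(a) mean_or_na(sub$grade[sub$accession == a]), 0)
  }, numeric(length(acc)))
  tp_means <- matrix(tp_means, nrow = length(acc),
                     dimnames = list(NULL, paste0("grade", tps, "h")))
  out <- data.frame(accession = acc, tp_means,
                    dsi = rowMeans(tp_means), # NA if any timepoint mean is NA
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dsi_table", "data.frame")
  out
}

#' Label extreme drought-resistant and drought-sensitive accessions
#'
#' The `k` accessions with the lowest DSI are labeled resistant (`"R"`),
#' the `k` highest sensitive (`"S"`), and the remainder intermediate. Ties
#' are broken by accession identifier (lexicographic), so the partition is
#' deterministic.
#'
#' @param dsi a `dsi_table` from [compute_dsi()].
#' @param k number of extremes per tail.
#' @param max_replicate_sd optional cap on the replicate standard deviation
#'   of grades: accessions exceeding it are not eligible for the extreme
#'   groups (off by default; requires a `replicate_sd` column).
#' @return The table with a `resistance_class` column added.
#' @export
classify_extremes <- function(dsi, k = 20, max_replicate_sd = NULL) {
  stopifnot(is.data.frame(dsi), all(c("accession", "dsi") %in% names(dsi)))
  k <- check_count(k, "k", 0L)
  usable <- which(!is.na(dsi$dsi))
  if (!is.null(max_replicate_sd) && !is.null(dsi$replicate_sd))
    usable <- usable[dsi$replicate_sd[usable] <= max_replicate_sd]
  if (2 * k > length(usable))
    stop_named("invalid_argument",
               "2k = %d exceeds the %d accessions with usable DSI",
               2 * k, length(usable))
  ord <- usable[order(dsi$dsi[usable], dsi$accession[usable])]
  cls <- rep("intermediate", nrow(dsi))
  if (k > 0) {
    cls[ord[seq_len(k)]] <- "R"
    cls[ord[seq(length(ord) - k + 1L, length(ord))]] <- "S"
  }
  dsi$resistance_class <- cls
  dsi
}

#' Cohort summary of the drought-sensitivity index
#'
#' @param dsi a `dsi_table` (or any data.frame with a `dsi` column).
#' @param below count accessions with DSI strictly below this value.
#' @param above count accessions with DSI strictly above this value.
#' @return list with `n`, `mean`, `sd`, `cv` (sample SD / mean), `n_below`
#'   and `n_above`.
#' @export
dsi_summary <- function(dsi, below = 1, above = 2.5) {
  v <- dsi$dsi[!is.na(dsi$dsi)]
  if (length(v) < 2) stop_named("invalid_argument", "need >= 2 non-NA DSI values")
  list(n = length(v), mean = mean(v), sd = stats::sd(v),
       cv = stats::sd(v) / mean(v),
       n_below = sum(v < below), n_above = sum(v > above))
}
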