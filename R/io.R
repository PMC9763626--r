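# Standard-format I/O: minimal VCF 4.2, TSV tables with provenance
# headers, and the ground-truth JSON.

#' Write a genotype matrix as minimal VCF 4.2
#'
#' CHROM, POS, ID, REF, ALT, QUAL ".", FILTER "PASS", INFO ".", FORMAT GT;
#' unphased genotypes 0/0, 0/1, 1/1 and ./. for missing.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(G$dosages), ncol = ncol(G$dosages))
  ok <- !is.na(G$dosages)
  gt[ok] <- gt_codes[G$dosages[ok] + 1L]
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses biallelic SNP records (GT field) into alternate-allele dosages;
#' `./.` becomes missing and phased separators are accepted. Multiallelic
#' records are rejected with the offending CHROM:POS in the error message.
#'
#' @param path VCF 4.2 file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_named("file_not_found", "no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  alt <- fx[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    w <- which(multi)[1]
    stop_named("multiallelic_record",
               "multiallelic record at %s:%s (ALT = %s)",
               fx[w, "CHROM"], fx[w, "POS"], alt[w])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_named("missing_gt", "VCF has no GT field")
  dose <- function(s) {
    s <- gsub("|", "/", s, fixed = TRUE)
    out <- rep(NA_integer_, length(s))
    out[s == "0/0"] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s == "1/1"] <- 2L
    out
  }
  D <- apply(gt, 2, dose)                   # variants x samples -> per sample
  D <- t(matrix(D, nrow = nrow(gt), dimnames = dimnames(gt)))
  variants <- data.frame(chrom = fx[, "CHROM"],
                         pos = as.integer(fx[, "POS"]),
                         ref = fx[, "REF"], alt = alt,
                         id = ifelse(is.na(fx[, "ID"]) | fx[, "ID"] == ".",
                                     paste0(fx[, "CHROM"], ":", fx[, "POS"]),
                                     fx[, "ID"]),
                         stringsAsFactors = FALSE)
  genotype_matrix(D, variants, rownames(D))
}

# TSV with '#'-prefixed provenance/metadata lines
write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a metabolite matrix as TSV
#'
#' Layout: features in rows, samples in columns; a `#condition` metadata
#' line carries the per-sample condition and a `#group` line the
#' resistance class.
#'
#' @param M a [metabolite_matrix()].
#' @param path file path.
#' @return `path` (write) or a `metabolite_matrix` (read).
#' @export
write_metabolite_tsv <- function(M, path) {
  stopifnot(inherits(M, "metabolite_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#condition\t",
                    paste(M$sample_meta$condition, collapse = "\t")), con)
  writeLines(paste0("#group\t",
                    paste(M$sample_meta$group, collapse = "\t")), con)
  writeLines(paste0("#accession\t",
                    paste(M$sample_meta$accession, collapse = "\t")), con)
  df <- data.frame(feature = M$feature_meta$id,
                   t(M$abundances), check.names = FALSE)
  colnames(df) <- c("feature", rownames(M$abundances))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_tsv
#' @export
read_metabolite_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  parse_meta <- function(tag) {
    ln <- meta[startsWith(meta, paste0("#", tag))]
    if (!length(ln)) return(NULL)
    strsplit(ln[1], "\t")[[1]][-1]
  }
  cond <- parse_meta("condition")
  grp <- parse_meta("group")
  acc <- parse_meta("accession")
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  A <- t(as.matrix(body[, -1, drop = FALSE]))
  colnames(A) <- body$feature
  n <- nrow(A)
  metabolite_matrix(A, data.frame(
    sample = rownames(A),
    accession = acc %||% rownames(A),
    condition = cond %||% rep("CK", n),
    group = grp %||% rep("intermediate", n),
    stringsAsFactors = FALSE))
}

#' Write the simulation ground truth as JSON
#'
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
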