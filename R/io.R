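#' File formats
#'
#' All tabular formats are plain tab-separated text with a header line:
#'
#' * manifest: `snp_id`, `chrom`, `pos` (1-based bp), `gc` (fraction in
#'   \[0,1\] for a window around the SNP);
#' * signal ("final report" style, long): `sample`, `snp_id`, `lrr`, `baf`;
#' * metadata: `sample`, `breed`;
#' * calls: `sample`, `chrom`, `start`, `end`, `copy_state`, `n_snps`, `lbf`,
#'   `profile`;
#' * CNVRs: `id`, `chrom`, `start`, `end`, `length`, `n_constituent_calls`,
#'   `source`;
#' * genotype matrix: first column `cnvr_id`, one column per sample, cells in
#'   `{0,1,2,3,4,NA}`.
#'
#' @name formats
NULL

#' Load a SNP manifest
#'
#' Reads the manifest TSV, drops non-autosomal SNPs (chrX/Un/MT and the like)
#' with a logged count, and checks that positions are strictly increasing
#' within each chromosome and GC fractions lie in \[0,1\].
#'
#' @param path manifest TSV.
#' @return `data.frame` with `snp_id`, `chrom`, `pos`, `gc`.
#' @export
load_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "gc")
  if (!all(need %in% names(df))) {
    .stopf("manifest must have columns %s", paste(need, collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  keep <- is_autosome(df$chrom)
  if (any(!keep)) {
    .log_filter("manifest non-autosomal SNPs", sum(!keep), sum(keep))
  }
  df <- df[keep, need, drop = FALSE]
  validate_manifest(df)
  rownames(df) <- NULL
  df
}

#' Validate a SNP manifest
#' @param manifest manifest data.frame.
#' @return the manifest, invisibly.
#' @export
validate_manifest <- function(manifest) {
  if (nrow(manifest) == 0) .stopf("empty manifest")
  if (anyDuplicated(manifest$snp_id)) .stopf("duplicated snp_id in manifest")
  if (any(manifest$gc < 0 | manifest$gc > 1, na.rm = TRUE)) {
    .stopf("manifest gc outside [0,1]")
  }
  for (ch in unique(manifest$chrom)) {
    p <- manifest$pos[manifest$chrom == ch]
    if (any(diff(p) <= 0)) {
      .stopf("manifest positions not strictly increasing on chrom %s", ch)
    }
  }
  invisible(manifest)
}

#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a sample signal
#'
#' @param sample sample id.
#' @param lrr,baf numeric vectors aligned to the manifest (NA = missing).
#' @param breed breed label (optional).
#' @return object of class `sample_signal`.
#' @export
sample_signal <- function(sample, lrr, baf, breed = NA_character_) {
  if (length(lrr) != length(baf)) .stopf("lrr and baf lengths differ")
  ok <- !is.na(baf)
  if (any(baf[ok] < 0 | baf[ok] > 1)) .stopf("baf outside [0,1]")
  structure(list(sample = sample, breed = breed,
                 lrr = as.numeric(lrr), baf = as.numeric(baf)),
            class = "sample_signal")
}

#' Load a long-format signal table
#'
#' Columns `sample`, `snp_id`, `lrr`, `baf`. Every `snp_id` must be present in
#' the manifest (unknown ids are a hard error naming the id). Vectors are
#' returned ordered as the manifest, with absent SNPs recorded as missing
#' (`NA`), never as zero. A sample missing more than `max_missing` of the
#' manifest is rejected as ragged.
#'
#' @param path signal TSV.
#' @param manifest manifest data.frame.
#' @param max_missing maximum tolerated missing fraction per sample (0.05).
#' @return named list of [sample_signal()] objects.
#' @export
load_signal_table <- function(path, manifest, max_missing = 0.05) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "snp_id", "lrr", "baf")
  if (!all(need %in% names(df))) {
    .stopf("signal table must have columns %s", paste(need, collapse = ", "))
  }
  idx <- match(df$snp_id, manifest$snp_id)
  if (anyNA(idx)) {
    .stopf("signal table references snp_id absent from manifest: %s",
           df$snp_id[which(is.na(idx))[1]])
  }
  n <- nrow(manifest)
  out <- list()
  for (s in unique(df$sample)) {
    rows <- df$sample == s
    lrr <- rep(NA_real_, n)
    baf <- rep(NA_real_, n)
    lrr[idx[rows]] <- df$lrr[rows]
    baf[idx[rows]] <- df$baf[rows]
    missing_frac <- mean(is.na(lrr) & is.na(baf))
    if (missing_frac > max_missing) {
      .stopf("ragged sample '%s': missing %.1f%% of manifest SNPs (max %.1f%%)",
             s, 100 * missing_frac, 100 * max_missing)
    }
    out[[s]] <- sample_signal(s, lrr, baf)
  }
  out
}

#' Write a cohort of signals as a long-format signal table
#' @param signals named list of `sample_signal`.
#' @param manifest manifest data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, manifest, path) {
  parts <- lapply(signals, function(sg) {
    keep <- !(is.na(sg$lrr) & is.na(sg$baf))
    data.frame(sample = sg$sample, snp_id = manifest$snp_id[keep],
               lrr = sg$lrr[keep], baf = sg$baf[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load sample metadata (sample -> breed)
#' @param path metadata TSV with columns `sample`, `breed`.
#' @return data.frame.
#' @export
load_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "breed") %in% names(df))) {
    .stopf("metadata must have columns sample, breed")
  }
  if (anyDuplicated(df$sample)) .stopf("duplicated sample in metadata")
  df
}

#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write call tables
#' @param path TSV path.
#' @return data.frame of calls.
#' @export
load_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname load_calls
#' @param calls call data.frame.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write CNVR tables
#' @param path TSV path.
#' @return data.frame of CNVRs.
#' @export
load_cnvrs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname load_cnvrs
#' @param cnvrs CNVR data.frame.
#' @export
write_cnvrs <- function(cnvrs, path) {
  utils::write.table(cnvrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the CNVR genotype matrix
#'
#' Rows are CNVRs, columns samples, cells copy states in `{0,1,2,3,4}` (NA
#' allowed). On disk the first column is `cnvr_id`.
#'
#' @param path TSV path.
#' @return integer matrix with rownames = CNVR ids, colnames = samples.
#' @export
load_genotype_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname load_genotype_matrix
#' @param m genotype matrix.
#' @export
write_genotype_matrix <- function(m, path) {
  df <- data.frame(cnvr_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
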