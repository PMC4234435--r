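#' GC-wave correction of the Log R ratio
#'
#' Fits, per sample, an ordinary least-squares regression of LRR on the
#' manifest's local GC fraction over non-missing SNPs and removes the fitted
#' slope while preserving the sample mean:
#' `corrected = lrr - b * (gc - mean(gc))`. GC-correlated long-range
#' "waviness" in array intensities is thereby flattened before quality
#' metrics and segmentation. With a zero-variance GC track the signal is
#' returned unchanged; with fewer than 100 non-missing SNPs a warning is
#' emitted and no correction applied.
#'
#' @param signal a [sample_signal()].
#' @param manifest manifest data.frame aligned to the signal.
#' @return corrected `sample_signal` (same length, same missing mask).
#' @export
gc_correct_lrr <- function(signal, manifest) {
  if (length(signal$lrr) != nrow(manifest)) {
    .stopf("signal/manifest length mismatch")
  }
  ok <- !is.na(signal$lrr) & !is.na(manifest$gc)
  if (sum(ok) < 100) {
    .warnf("sample '%s': fewer than 100 non-missing SNPs, no GC correction",
           signal$sample)
    return(signal)
  }
  gc <- manifest$gc[ok]
  if (stats::var(gc) == 0) return(signal)
  b <- stats::cov(signal$lrr[ok], gc) / stats::var(gc)
  out <- signal
  out$lrr[ok] <- signal$lrr[ok] - b * (gc - mean(gc))
  out
}

#' Waviness factor of a corrected signal
#'
#' The waviness factor (WF) summarises long-range, GC-correlated undulation of
#' the LRR track. Definition used here: bin the genome into 1 Mb windows, take
#' the median corrected LRR per window, and report
#' `sd(window medians) * sign(cor(window medians, window mean GC))`.
#' The magnitude lives on the same ~0.04 scale as the common per-sample QC
#' heuristic for genomic waves; the sign encodes the GC direction of the wave.
#'
#' @param signal corrected `sample_signal`.
#' @param manifest manifest data.frame.
#' @param window_bp window size (default 1 Mb).
#' @return signed waviness factor (0 when fewer than 2 usable windows).
#' @export
waviness_factor <- function(signal, manifest, window_bp = 1e6) {
  ok <- !is.na(signal$lrr)
  if (!any(ok)) .stopf("all-missing LRR for sample '%s'", signal$sample)
  win <- paste(manifest$chrom[ok], (manifest$pos[ok] - 1) %/% window_bp)
  med <- tapply(signal$lrr[ok], win, stats::median)
  gcw <- tapply(manifest$gc[ok], win, mean)
  if (length(med) < 2) return(0)
  s <- stats::sd(med)
  if (s == 0) return(0)
  r <- suppressWarnings(stats::cor(as.numeric(med), as.numeric(gcw)))
  sgn <- if (is.na(r) || r >= 0) 1 else -1
  s * sgn
}

#' Per-sample quality report
#'
#' Computes the QC metrics on the *corrected* signal and applies the standard
#' sample filters: a sample passes iff `sd(LRR) < sd_lrr_max`,
#' `|WF| <= wf_abs_max`, and its raw P-profile call count is *strictly below*
#' `max_cnvs_per_sample` (a sample with exactly 40 calls fails, matching the
#' "40 or more" rule).
#'
#' @param signal corrected `sample_signal`.
#' @param manifest manifest data.frame.
#' @param n_cnvs raw autosomal P-profile call count for the sample (before
#'   SNP-count/LBF filtering).
#' @param sd_lrr_max,wf_abs_max,max_cnvs_per_sample thresholds (defaults
#'   0.25 / 0.04 / 40).
#' @return one-row data.frame: `sample`, `sd_lrr`, `wf`, `n_cnvs`, `passed`,
#'   `reasons` (comma-separated failure labels, "" when passed).
#' @export
compute_qc <- function(signal, manifest, n_cnvs,
                       sd_lrr_max = 0.25, wf_abs_max = 0.04,
                       max_cnvs_per_sample = 40) {
  ok <- !is.na(signal$lrr)
  if (!any(ok)) .stopf("all-missing LRR for sample '%s'", signal$sample)
  sd_lrr <- if (sum(ok) > 1) stats::sd(signal$lrr[ok]) else 0
  wf <- waviness_factor(signal, manifest)
  reasons <- character(0)
  if (!(sd_lrr < sd_lrr_max)) reasons <- c(reasons, "sd_lrr")
  if (!(abs(wf) <= wf_abs_max)) reasons <- c(reasons, "wf")
  if (!(n_cnvs < max_cnvs_per_sample)) reasons <- c(reasons, "n_cnvs")
  data.frame(sample = signal$sample, sd_lrr = sd_lrr, wf = wf,
             n_cnvs = as.integer(n_cnvs), passed = length(reasons) == 0,
             reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Partition samples by their QC reports
#'
#' Failed samples must be removed from *both* caller profiles downstream.
#'
#' @param reports data.frame of rows from [compute_qc()] (one per sample).
#' @return list with `passed` and `failed` character vectors of sample ids
#'   and the `reports` table.
#' @export
filter_samples <- function(reports) {
  if (anyDuplicated(reports$sample)) .stopf("duplicate QC report for a sample")
  passed <- reports$sample[reports$passed]
  failed <- reports$sample[!reports$passed]
  .log_filter("sample QC", length(failed), length(passed))
  list(passed = passed, failed = failed, reports = reports)
}

#' Run QC across a cohort
#'
#' GC-corrects every signal, obtains raw P-profile call counts (needed for the
#' call-count criterion), and applies [compute_qc()] / [filter_samples()].
#'
#' @param signals named list of `sample_signal`.
#' @param manifest manifest data.frame.
#' @param p_call_counts named integer vector: raw P-profile calls per sample.
#' @param config a [run_config()].
#' @return list: `corrected` (signals), `reports`, `passed`, `failed`.
#' @export
qc_cohort <- function(signals, manifest, p_call_counts, config = run_config()) {
  corrected <- lapply(signals, gc_correct_lrr, manifest = manifest)
  reports <- do.call(rbind, lapply(corrected, function(sg) {
    compute_qc(sg, manifest,
               n_cnvs = p_call_counts[[sg$sample]] %||% 0L,
               sd_lrr_max = config$sd_lrr_max,
               wf_abs_max = config$wf_abs_max,
               max_cnvs_per_sample = config$max_cnvs_per_sample)
  }))
  rownames(reports) <- NULL
  part <- filter_samples(reports)
  list(corrected = corrected, reports = reports,
       passed = part$passed, failed = part$failed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
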