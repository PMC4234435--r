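#' Merge CNV calls into CNV regions (CNVRs)
#'
#' Single-linkage union of overlapping call intervals across all samples of
#' one profile: a CNVR's breakpoints are the outermost boundaries of all the
#' constituent calls. Overlap is on closed intervals (>= 1 shared base);
#' adjacent-but-not-overlapping calls (1 bp gap, no shared base) are *not*
#' merged. The operation is idempotent and order-independent.
#'
#' @param calls call data.frame from one profile (any samples); an interval
#'   table also works.
#' @param source label recorded in the `source` column (defaults to the
#'   calls' profile when present).
#' @return CNVR data.frame: `id`, `chrom`, `start`, `end`, `length`
#'   (`end - start`), `n_constituent_calls`, `source`, `constituents`
#'   (comma-separated input row indices).
#' @export
merge_calls_to_cnvrs <- function(calls, source = NULL) {
  if (is.null(source)) {
    source <- if ("profile" %in% names(calls) && nrow(calls) > 0) {
      calls$profile[1]
    } else "unknown"
  }
  if (nrow(calls) == 0) {
    return(data.frame(id = integer(), chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      n_constituent_calls = integer(), source = character(),
                      constituents = character(), stringsAsFactors = FALSE))
  }
  gr <- as_granges(calls)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  members <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE)
  df$length <- cnvr_length(df$start, df$end)
  df$n_constituent_calls <- lengths(members)[as.character(seq_len(nrow(df)))]
  df$source <- source
  df$constituents <- vapply(
    members[as.character(seq_len(nrow(df)))],
    function(i) paste(sort(i), collapse = ","), "")
  df <- df[order(suppressWarnings(as.integer(df$chrom)), df$start), ,
           drop = FALSE]
  df <- cbind(id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Dual-profile CNVR consensus
#'
#' Retains each Q-profile CNVR having at least `min_overlap_bp` inclusive
#' overlap with at least one P-profile CNVR; the kept regions keep the
#' *Q-profile boundaries* (the P set only certifies them). Requiring both
#' profiles to recover a region reduces the false discovery rate; the default
#' 10 kb threshold is the standard cross-caller/published-set overlap rule.
#'
#' @param q_cnvrs,p_cnvrs merged CNVR tables from [merge_calls_to_cnvrs()].
#' @param min_overlap_bp minimum inclusive overlap in bp (default 10000).
#' @return consensus CNVR data.frame (Q rows, re-numbered), with a
#'   `witness_p_id` column naming one P CNVR satisfying the overlap rule.
#' @export
consensus_cnvrs <- function(q_cnvrs, p_cnvrs, min_overlap_bp = 10000) {
  if (nrow(q_cnvrs) == 0 || nrow(p_cnvrs) == 0) {
    out <- q_cnvrs[integer(0), , drop = FALSE]
    out$witness_p_id <- integer(0)
    return(out)
  }
  hits <- find_interval_overlaps(q_cnvrs, p_cnvrs,
                                 minoverlap = min_overlap_bp)
  qh <- S4Vectors::queryHits(hits)
  keep <- sort(unique(qh))
  witness <- vapply(keep, function(i) {
    p_cnvrs$id[min(S4Vectors::subjectHits(hits)[qh == i])]
  }, numeric(1))
  out <- q_cnvrs[keep, , drop = FALSE]
  out$witness_p_id <- witness
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
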