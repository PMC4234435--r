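#' Genotype samples at consensus CNVRs
#'
#' Every (QC-passed) sample is genotyped at every consensus CNVR from the
#' relaxed Q-profile call list: a cell holds the copy state of the sample's
#' relaxed call assigned to that CNVR, and 2 (diploid) otherwise. A call is
#' assigned to the CNVR it overlaps most (>= 1 bp, inclusive count;
#' largest-overlap wins, ties broken deterministically by (chrom, start)).
#' When two calls of one sample land on the same CNVR, the state of the
#' larger-overlap call wins. Individual calls may be smaller or larger than
#' the CNVR; overlap-based assignment (rather than strict containment) keeps
#' carriers whose relaxed call slightly overhangs the region envelope. The
#' supporting call index for every non-diploid cell is kept for audit.
#'
#' @param cnvrs consensus CNVR table (columns `id`, `chrom`, `start`, `end`).
#' @param relaxed_calls filtered relaxed Q-profile calls.
#' @param samples character vector of sample ids (QC-passed cohort).
#' @param rule `"overlap"` (default, >= 1 bp) or `"contain"` (call fully
#'   within the CNVR).
#' @return object of class `cnvr_genotypes`: list with `matrix` (CNVRs x
#'   samples, states 0..4), `support` (data.frame cnvr_id, sample, call_row,
#'   copy_state, overlap_bp), `cnvrs`.
#' @export
genotype_samples <- function(cnvrs, relaxed_calls, samples,
                             rule = c("overlap", "contain")) {
  rule <- match.arg(rule)
  if (nrow(relaxed_calls) > 0 &&
      !all(relaxed_calls$sample %in% samples)) {
    .stopf("call from sample not in the sample list: %s",
           setdiff(relaxed_calls$sample, samples)[1])
  }
  m <- matrix(2L, nrow = nrow(cnvrs), ncol = length(samples),
              dimnames = list(as.character(cnvrs$id), samples))
  support <- data.frame(cnvr_id = numeric(), sample = character(),
                        call_row = integer(), copy_state = integer(),
                        overlap_bp = numeric(), stringsAsFactors = FALSE)
  if (nrow(relaxed_calls) > 0 && nrow(cnvrs) > 0) {
    type <- if (rule == "contain") "within" else "any"
    hits <- find_interval_overlaps(relaxed_calls, cnvrs, type = type)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh) > 0) {
      ov <- pmin(relaxed_calls$end[qh], cnvrs$end[sh]) -
        pmax(relaxed_calls$start[qh], cnvrs$start[sh]) + 1
      # per call: keep the largest-overlap CNVR (tie -> lower (chrom, start),
      # i.e. the first row in the sorted CNVR table)
      ord <- order(qh, -ov, sh)
      first <- !duplicated(qh[ord])
      qh <- qh[ord][first]; sh <- sh[ord][first]; ov <- ov[ord][first]
      # per (sample, cnvr): the larger-overlap call wins
      key <- paste(relaxed_calls$sample[qh], sh)
      ord2 <- order(key, -ov, qh)
      first2 <- !duplicated(key[ord2])
      qh <- qh[ord2][first2]; sh <- sh[ord2][first2]; ov <- ov[ord2][first2]
      m[cbind(sh, match(relaxed_calls$sample[qh], samples))] <-
        as.integer(relaxed_calls$copy_state[qh])
      support <- data.frame(cnvr_id = cnvrs$id[sh],
                            sample = relaxed_calls$sample[qh],
                            call_row = qh,
                            copy_state = as.integer(relaxed_calls$copy_state[qh]),
                            overlap_bp = ov, stringsAsFactors = FALSE)
    }
  }
  structure(list(matrix = m, support = support, cnvrs = cnvrs),
            class = "cnvr_genotypes")
}

#' Carrier count per CNVR
#' @param m genotype matrix (states 0..4).
#' @return integer vector of non-diploid cell counts per row.
#' @export
carrier_counts <- function(m) {
  as.integer(rowSums(m != 2L, na.rm = TRUE))
}

#' Remove singleton CNVRs
#'
#' A CNVR carried by exactly one sample is a singleton. Singletons are more
#' likely false positives than regions seen in two or more independent
#' individuals and are excluded from the final list (conservative choice);
#' they are returned separately, and zero-carrier CNVRs (possible when no
#' relaxed call reaches a stringent region) are retained but flagged.
#'
#' @param m genotype matrix.
#' @return list: `matrix` (retained rows), `singletons` (row names removed),
#'   `zero_carrier` (row names retained but without carriers).
#' @export
remove_singletons <- function(m) {
  cc <- carrier_counts(m)
  singletons <- rownames(m)[cc == 1L]
  zero <- rownames(m)[cc == 0L]
  if (length(zero) > 0) {
    message(sprintf("[genotype] %d zero-carrier CNVR(s) flagged: %s",
                    length(zero), paste(zero, collapse = ",")))
  }
  keep <- cc != 1L
  .log_filter("singleton CNVRs", sum(!keep), sum(keep))
  list(matrix = m[keep, , drop = FALSE], singletons = singletons,
       zero_carrier = zero)
}

#' Classify CNVR types from the genotype matrix
#'
#' A CNVR is a pure deletion when every non-diploid genotype is a het/hom
#' deletion (states 0/1), a pure duplication when all are het/hom duplications
#' (3/4), and `del/dupl` when both occur. Zero-carrier rows are
#' `undetermined` and excluded from the type counts.
#'
#' @param m genotype matrix.
#' @param lengths optional named lengths (bp) per CNVR id.
#' @return data.frame: `cnvr_id`, `type`, `carriers`, `frequency`, `length`,
#'   `singleton`.
#' @export
classify_cnvr_types <- function(m, lengths = NULL) {
  cc <- carrier_counts(m)
  type <- vapply(seq_len(nrow(m)), function(i) {
    g <- m[i, ]
    g <- g[!is.na(g) & g != 2L]
    if (length(g) == 0) return("undetermined")
    has_del <- any(g <= 1L)
    has_dup <- any(g >= 3L)
    if (has_del && has_dup) "del/dupl" else if (has_del) "del" else "dupl"
  }, "")
  df <- data.frame(cnvr_id = rownames(m), type = type, carriers = cc,
                   frequency = round_half_up(cc / ncol(m), 2),
                   stringsAsFactors = FALSE)
  if (!is.null(lengths)) df$length <- unname(lengths[rownames(m)])
  df$singleton <- cc == 1L
  df
}

#' Size summary of a CNVR set
#'
#' Histogram of lengths in `bin_width` bins (bins `[k*w, (k+1)*w)`, labelled
#' by their lower edge), counts in the conventional strata — below 100 kb
#' (`[0, 1e5)`), 100 kb to 1 Mb inclusive (`[1e5, 1e6]`), above 1 Mb
#' (`(1e6, Inf)`) — and medians overall and per type.
#'
#' @param summaries data.frame with `length` and `type` columns (e.g. from
#'   [classify_cnvr_types()]), lengths computed as `end - start`.
#' @param bin_width histogram bin width in bp (default 50 kb).
#' @return list: `histogram` (data.frame bin_start, count), `strata`
#'   (named counts `lt_100kb`, `kb100_to_1mb`, `gt_1mb`), `median_all`,
#'   `median_by_type`, `min_length`, `n`.
#' @export
summarize_sizes <- function(summaries, bin_width = 50000) {
  len <- summaries$length
  if (length(len) == 0) {
    return(list(histogram = data.frame(bin_start = numeric(),
                                       count = integer()),
                strata = c(lt_100kb = 0L, kb100_to_1mb = 0L, gt_1mb = 0L),
                median_all = NA_real_, median_by_type = numeric(0),
                min_length = NA_real_, n = 0L))
  }
  bins <- floor(len / bin_width) * bin_width
  tab <- table(bins)
  histogram <- data.frame(bin_start = as.numeric(names(tab)),
                          count = as.integer(tab))
  strata <- c(lt_100kb = sum(len < 1e5),
              kb100_to_1mb = sum(len >= 1e5 & len <= 1e6),
              gt_1mb = sum(len > 1e6))
  med_by_type <- tapply(len, summaries$type, stats::median)
  list(histogram = histogram, strata = strata,
       median_all = stats::median(len),
       median_by_type = med_by_type,
       min_length = min(len), n = length(len))
}

#' Compare deletion and duplication lengths
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on raw CNVR lengths,
#' deletions vs duplications.
#'
#' @param summaries data.frame with `length` and `type`.
#' @return list: `t`, `df`, `p_value`, group sizes and medians.
#' @export
compare_del_dup_lengths <- function(summaries) {
  del <- summaries$length[summaries$type == "del"]
  dup <- summaries$length[summaries$type == "dupl"]
  if (length(del) < 2 || length(dup) < 2) {
    .stopf("need at least 2 deletions and 2 duplications (have %d and %d)",
           length(del), length(dup))
  }
  tt <- stats::t.test(del, dup, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_del = length(del), n_dup = length(dup),
       median_del = stats::median(del), median_dup = stats::median(dup))
}
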