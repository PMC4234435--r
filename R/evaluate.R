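#' Truth-recovery evaluation for synthetic cohorts
#'
#' Compares pipeline output against the planted truth of a synthetic cohort.
#' [truth_recovery()] asks which planted variants are recovered as consensus
#' CNVRs with at least `min_overlap_bp` inclusive overlap;
#' [genotype_accuracy()] asks, for every (variant, carrier) pair whose
#' carrier is in the genotyped cohort, whether the genotype matrix holds the
#' planted copy state at the best-overlapping CNVR. Pairs whose carriers
#' failed QC are excluded (they are outside the genotyped cohort by design).
#'
#' @param truths truth table from [plant_truth_cnvs()].
#' @param cnvrs consensus CNVR table.
#' @param min_overlap_bp inclusive overlap to count a variant as recovered
#'   (default 10000).
#' @param min_snps only evaluate planted variants spanning at least this many
#'   SNPs (default 1 = all).
#' @param cohort optional character vector of the samples that entered
#'   calling (the QC-passed cohort). When given, a planted variant none of
#'   whose carriers are in this cohort is *undiscoverable* (its signal was
#'   removed with its carriers, exactly as in a real screen) and is reported
#'   separately rather than entering the recovery denominator.
#' @return `truth_recovery`: list with `n_eval`, `n_recovered`, `rate`
#'   (over discoverable variants), `n_undiscoverable`, `rate_unconditional`
#'   (over all evaluated variants), and the per-variant logical `recovered`.
#' @export
truth_recovery <- function(truths, cnvrs, min_overlap_bp = 10000,
                           min_snps = 1, cohort = NULL) {
  ev <- truths[truths$n_snps >= min_snps, , drop = FALSE]
  if (nrow(ev) == 0) .stopf("no truth variants to evaluate")
  hit <- rep(FALSE, nrow(ev))
  if (nrow(cnvrs) > 0) {
    hits <- find_interval_overlaps(ev, cnvrs, minoverlap = min_overlap_bp)
    hit[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  discoverable <- rep(TRUE, nrow(ev))
  if (!is.null(cohort)) {
    discoverable <- vapply(seq_len(nrow(ev)), function(r) {
      any(truth_carriers(ev[r, ]) %in% cohort)
    }, logical(1))
  }
  list(n_eval = sum(discoverable),
       n_recovered = sum(hit & discoverable),
       rate = sum(hit & discoverable) / max(1L, sum(discoverable)),
       n_undiscoverable = sum(!discoverable),
       rate_unconditional = mean(hit),
       recovered = stats::setNames(hit, ev$truth_id))
}

#' @rdname truth_recovery
#' @param genotypes a `cnvr_genotypes` object (or its final matrix) from
#'   [genotype_samples()]; rownames are CNVR ids of `cnvrs`.
#' @param m genotype matrix whose columns are the genotyped samples.
#' @return `genotype_accuracy`: list with `n_pairs`, `n_correct`, `accuracy`.
#' @export
genotype_accuracy <- function(truths, cnvrs, m, min_snps = 1) {
  ev <- truths[truths$n_snps >= min_snps, , drop = FALSE]
  n_pairs <- 0L
  n_correct <- 0L
  present <- cnvrs[as.character(cnvrs$id) %in% rownames(m), , drop = FALSE]
  for (r in seq_len(nrow(ev))) {
    carriers <- intersect(truth_carriers(ev[r, ]), colnames(m))
    if (length(carriers) == 0) next
    # best-overlapping genotyped CNVR for this truth interval
    ov <- ifelse(present$chrom == ev$chrom[r],
                 pmin(present$end, ev$end[r]) -
                   pmax(present$start, ev$start[r]) + 1, 0)
    n_pairs <- n_pairs + length(carriers)
    if (all(ov <= 0)) next
    row_id <- as.character(present$id[which.max(ov)])
    n_correct <- n_correct +
      sum(m[row_id, carriers] == ev$copy_state[r])
  }
  if (n_pairs == 0) .stopf("no (variant, carrier) pairs in the cohort")
  list(n_pairs = n_pairs, n_correct = n_correct,
       accuracy = n_correct / n_pairs)
}
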