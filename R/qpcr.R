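#' Delta-delta-Ct relative quantification
#'
#' Implements the standard 2^-ddCt arithmetic for copy-number estimation from
#' real-time PCR threshold cycles, assuming an amplification efficiency of
#' 2.0 per cycle (primer pairs are assumed efficiency-calibrated upstream):
#'
#' * `dCt  = mean(target Cts) - mean(reference-gene Cts)` for one individual;
#' * `ddCt = dCt(tested individual) - dCt(reference individual)`, the
#'   reference individual being one without any deletion or duplication at
#'   the tested loci;
#' * `copy number estimate = 2 * 2^(-ddCt)` (2 at ddCt = 0, halved per extra
#'   cycle).
#'
#' @param target_cts numeric replicate Ct values at the tested locus
#'   (>= 2 finite replicates required; quadruplicates typical).
#' @param refgene_cts replicate Ct values of the reference gene, same sample.
#' @param ref_individual_delta_ct the reference individual's dCt at this
#'   locus.
#' @param sample,locus identifiers carried through to the result.
#' @return one-row data.frame: `sample`, `locus`, `delta_ct`,
#'   `delta_delta_ct`, `copy_number_estimate`, `copy_class`.
#' @export
delta_delta_ct <- function(target_cts, refgene_cts, ref_individual_delta_ct,
                           sample = NA_character_, locus = NA_character_) {
  target_cts <- target_cts[is.finite(target_cts)]
  refgene_cts <- refgene_cts[is.finite(refgene_cts)]
  if (length(target_cts) < 2 || length(refgene_cts) < 2) {
    .stopf("need >= 2 finite Ct replicates (have %d target, %d reference)",
           length(target_cts), length(refgene_cts))
  }
  if (any(c(target_cts, refgene_cts) <= 0)) .stopf("Ct values must be > 0")
  dct <- mean(target_cts) - mean(refgene_cts)
  ddct <- dct - ref_individual_delta_ct
  est <- 2 * 2^(-ddct)
  data.frame(sample = sample, locus = locus, delta_ct = dct,
             delta_delta_ct = ddct, copy_number_estimate = est,
             copy_class = classify_copy_number(est),
             stringsAsFactors = FALSE)
}

#' Classify a continuous copy-number estimate
#'
#' Nearest-integer rounding (halves upward): 0 or 1 -> `del`, 2 -> `normal`,
#' 3 or more -> `dup`.
#'
#' @param estimate positive copy-number estimate(s).
#' @return character vector in `{del, normal, dup}`.
#' @export
classify_copy_number <- function(estimate) {
  if (any(estimate <= 0)) .stopf("copy-number estimate must be > 0")
  cn <- round_half_up(estimate)
  ifelse(cn <= 1, "del", ifelse(cn == 2, "normal", "dup"))
}

#' Map array copy states to qPCR classes
#' @param state integer copy states 0..4.
#' @return character vector in `{del, normal, dup}`.
#' @export
state_to_class <- function(state) {
  ifelse(state <= 1, "del", ifelse(state == 2, "normal", "dup"))
}

#' Array vs qPCR genotype concordance
#'
#' Compares matched sample-locus pairs: a mismatch is any disagreement of
#' class; a false positive is an array CNV read as normal by qPCR; a false
#' negative an array normal read as CNV. Concordance is
#' `100 * (n_tested - n_mismatch) / n_tested`, rounded half-up to an integer.
#'
#' @param array_class,qpcr_class equal-length character vectors in
#'   `{del, normal, dup}` for matched sample-locus pairs.
#' @return list: `n_tested`, `n_cnv_carriers`, `n_mismatch`, `false_pos`,
#'   `false_neg`, `concordance_pct`.
#' @export
concordance <- function(array_class, qpcr_class) {
  if (length(array_class) == 0) .stopf("no sample-locus pairs")
  if (length(array_class) != length(qpcr_class)) {
    .stopf("unmatched sample-locus pairs (%d vs %d)",
           length(array_class), length(qpcr_class))
  }
  mm <- array_class != qpcr_class
  list(n_tested = length(array_class),
       n_cnv_carriers = sum(array_class != "normal"),
       n_mismatch = sum(mm),
       false_pos = sum(array_class != "normal" & qpcr_class == "normal"),
       false_neg = sum(array_class == "normal" & qpcr_class != "normal"),
       concordance_pct = round_half_up(100 * mean(!mm)))
}

#' Per-CNVR validation rate
#'
#' A CNVR is validated when at least one array-carrier sample at that locus
#' has a concordant qPCR class. The rate is `100 * validated / tested`,
#' rounded half-up to an integer.
#'
#' @param outcomes data.frame with columns `locus`, `array_class`,
#'   `qpcr_class` (one row per tested sample-locus pair).
#' @return list: `n_validated`, `n_tested`, `rate_pct`, `unvalidated`
#'   (locus ids).
#' @export
validation_rate <- function(outcomes) {
  carriers <- outcomes[outcomes$array_class != "normal", , drop = FALSE]
  loci <- unique(carriers$locus)
  if (length(loci) == 0) .stopf("no CNVR with a tested carrier")
  validated <- vapply(loci, function(l) {
    any(carriers$array_class[carriers$locus == l] ==
          carriers$qpcr_class[carriers$locus == l])
  }, logical(1))
  list(n_validated = sum(validated), n_tested = length(loci),
       rate_pct = round_half_up(100 * sum(validated) / length(loci)),
       unvalidated = loci[!validated])
}

#' Read a Ct table
#'
#' CSV with columns `sample`, `locus`, `rep1` ... `repK` (K >= 2).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
load_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reps <- grep("^rep", names(df), value = TRUE)
  if (!all(c("sample", "locus") %in% names(df)) || length(reps) < 2) {
    .stopf("Ct table needs columns sample, locus, rep1..repK (K >= 2)")
  }
  df
}

#' Run ddCt quantification over a Ct table
#'
#' @param ct data.frame from [load_ct_table()]; the reference gene's rows
#'   carry `locus == ref_gene`.
#' @param ref_gene locus label of the reference gene.
#' @param ref_individual sample id of the no-CNV reference individual.
#' @return data.frame of [delta_delta_ct()] rows for every (sample, locus)
#'   pair with `locus != ref_gene`.
#' @export
qpcr_quantify <- function(ct, ref_gene, ref_individual) {
  reps <- grep("^rep", names(ct), value = TRUE)
  get_cts <- function(s, l) {
    r <- ct[ct$sample == s & ct$locus == l, reps, drop = FALSE]
    if (nrow(r) == 0) .stopf("no Ct rows for sample '%s' locus '%s'", s, l)
    as.numeric(r[1, ])
  }
  loci <- setdiff(unique(ct$locus), ref_gene)
  out <- list()
  for (l in loci) {
    ref_dct <- mean(get_cts(ref_individual, l), na.rm = TRUE) -
      mean(get_cts(ref_individual, ref_gene), na.rm = TRUE)
    for (s in setdiff(unique(ct$sample[ct$locus == l]), NA)) {
      out[[length(out) + 1L]] <- delta_delta_ct(
        get_cts(s, l), get_cts(s, ref_gene), ref_dct,
        sample = s, locus = l)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
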