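#' Per-breed CNVR frequencies
#'
#' For every CNVR and every breed with at least one affected sample:
#' `n_affected` carriers out of `n_screened` QC-passed samples of that breed,
#' with the frequency rounded half-up to 2 decimals in reports (5/12 -> 0.42).
#'
#' @param m genotype matrix (CNVRs x samples).
#' @param metadata data.frame `sample`, `breed` covering every column of `m`.
#' @return data.frame: `cnvr_id`, `breed`, `n_affected`, `n_screened`, `freq`.
#' @export
breed_frequencies <- function(m, metadata) {
  missing <- setdiff(colnames(m), metadata$sample)
  if (length(missing) > 0) .stopf("sample without breed: %s", missing[1])
  breed <- metadata$breed[match(colnames(m), metadata$sample)]
  screened <- table(breed)
  recs <- list()
  for (i in seq_len(nrow(m))) {
    aff <- colnames(m)[!is.na(m[i, ]) & m[i, ] != 2L]
    if (length(aff) == 0) next
    ab <- table(breed[match(aff, colnames(m))])
    for (b in names(ab)) {
      recs[[length(recs) + 1L]] <- data.frame(
        cnvr_id = rownames(m)[i], breed = b,
        n_affected = as.integer(ab[[b]]),
        n_screened = as.integer(screened[[b]]),
        freq = round_half_up(ab[[b]] / screened[[b]], 2),
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) {
    return(data.frame(cnvr_id = character(), breed = character(),
                      n_affected = integer(), n_screened = integer(),
                      freq = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Single-breed CNVRs, raw and stringent
#'
#' The raw list holds CNVRs whose carriers all belong to one breed. The
#' stringent list additionally removes raw entries that overlap (>=
#' `min_overlap_bp` inclusive) a published CNVR reported in a *different*
#' breed, or one lacking breed information (treated as unknown and therefore
#' excluded — prior reports in unnamed breeds cannot certify breed
#' exclusivity).
#'
#' @param freq_records output of [breed_frequencies()].
#' @param cnvrs CNVR table with `id`, `chrom`, `start`, `end` for the CNVRs in
#'   `freq_records`.
#' @param published interval table of published CNVRs, optionally with a
#'   `breed` attribute column (NA/absent = unknown breed); NULL for none.
#' @param min_overlap_bp inclusive overlap threshold (default 10000).
#' @return list: `raw` (data.frame `cnvr_id`, `breed`), `stringent` (subset
#'   of `raw`), `removed` (data.frame with a `reason` column).
#' @export
single_breed_cnvrs <- function(freq_records, cnvrs, published = NULL,
                               min_overlap_bp = 10000) {
  n_breeds <- table(freq_records$cnvr_id)
  raw_ids <- names(n_breeds)[n_breeds == 1L]
  raw <- freq_records[freq_records$cnvr_id %in% raw_ids,
                      c("cnvr_id", "breed"), drop = FALSE]
  rownames(raw) <- NULL
  if (nrow(raw) == 0 || is.null(published) || nrow(published) == 0) {
    return(list(raw = raw, stringent = raw,
                removed = cbind(raw[integer(0), , drop = FALSE],
                                reason = character(0))))
  }
  iv <- cnvrs[match(raw$cnvr_id, as.character(cnvrs$id)), , drop = FALSE]
  hits <- find_interval_overlaps(iv, published, minoverlap = min_overlap_bp)
  pub_breed <- if ("breed" %in% names(published)) published$breed
               else rep(NA_character_, nrow(published))
  reason <- rep(NA_character_, nrow(raw))
  for (k in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[k]
    pb <- pub_breed[S4Vectors::subjectHits(hits)[k]]
    if (is.na(pb) || !nzchar(pb)) {
      reason[i] <- "published breed unknown"
    } else if (pb != raw$breed[i] && is.na(reason[i])) {
      reason[i] <- "published in different breed"
    }
  }
  removed <- cbind(raw[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  stringent <- raw[is.na(reason), , drop = FALSE]
  rownames(stringent) <- rownames(removed) <- NULL
  list(raw = raw, stringent = stringent, removed = removed)
}

#' Frequency-stratified overlap with published CNVR sets
#'
#' For the strata all CNVRs / cohort frequency > 5% / >= 1% / < 1%, counts the
#' CNVRs having at least `min_overlap_bp` inclusive overlap with any interval
#' of the published union, with percentages rounded half-up to integers.
#' The >1% stratum is cumulative (it contains the >5% stratum), so the >1%
#' and <1% strata partition the full set. The exact boundary `freq == 0.01`
#' is placed in the >1% stratum.
#'
#' @param cnvrs CNVR table (`id`, `chrom`, `start`, `end`).
#' @param frequencies named cohort frequencies (carriers / cohort size) per
#'   CNVR id, *unrounded*.
#' @param published interval table (union of published sets).
#' @param min_overlap_bp inclusive overlap threshold (default 10000).
#' @param strata frequency boundaries, descending (default 0.05, 0.01).
#' @return data.frame: `stratum`, `n`, `n_overlap`, `pct_overlap`.
#' @export
stratified_published_overlap <- function(cnvrs, frequencies, published,
                                         min_overlap_bp = 10000,
                                         strata = c(0.05, 0.01)) {
  f <- frequencies[as.character(cnvrs$id)]
  overl <- rep(FALSE, nrow(cnvrs))
  if (!is.null(published) && nrow(published) > 0 && nrow(cnvrs) > 0) {
    hits <- find_interval_overlaps(cnvrs, published,
                                   minoverlap = min_overlap_bp)
    overl[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  hi <- strata[1]; lo <- strata[2]
  groups <- list(all = rep(TRUE, nrow(cnvrs)),
                 gt_hi = f > hi,
                 ge_lo = f >= lo,
                 lt_lo = f < lo)
  names(groups) <- c("all", sprintf("gt_%g", hi), sprintf("gt_%g", lo),
                     sprintf("lt_%g", lo))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    n <- sum(sel); n_ov <- sum(overl & sel)
    data.frame(stratum = g, n = n, n_overlap = n_ov,
               pct_overlap = if (n > 0) round_half_up(100 * n_ov / n)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Filter a gene table down to 1:1 dog-human orthologs
#'
#' Applies, in order: (1) drop genes without a human ortholog; (2) drop genes
#' on chromosome X, unknown or mitochondrial contigs; (3) drop dog gene ids
#' appearing more than once; (4) drop human ortholog ids appearing more than
#' once. Step counts are reported so the filtering ledger is auditable.
#'
#' @param genes data.frame: `gene_id`, `human_ortholog` (NA = none), `chrom`,
#'   `start`, `end`.
#' @return the filtered data.frame, with attribute `ledger` (named integer
#'   vector of row counts after each step).
#' @export
filter_orthologs <- function(genes) {
  ledger <- c(input = nrow(genes))
  g <- genes[!is.na(genes$human_ortholog) & nzchar(genes$human_ortholog), ,
             drop = FALSE]
  ledger <- c(ledger, with_ortholog = nrow(g))
  g <- g[is_autosome(g$chrom), , drop = FALSE]
  ledger <- c(ledger, autosomal = nrow(g))
  g <- g[!(g$gene_id %in% g$gene_id[duplicated(g$gene_id)]), , drop = FALSE]
  ledger <- c(ledger, unique_dog = nrow(g))
  duph <- g$human_ortholog[duplicated(g$human_ortholog)]
  g <- g[!(g$human_ortholog %in% duph), , drop = FALSE]
  ledger <- c(ledger, unique_human = nrow(g))
  rownames(g) <- NULL
  attr(g, "ledger") <- ledger
  g
}

#' Genes overlapping CNVRs
#'
#' Reports every (gene, CNVR) pair with at least `min_overlap_bp` inclusive
#' overlap (default 1 bp — CNVR breakpoints are rough envelope estimates, so
#' a liberal overlap rule is used) and flags genes lying fully within the
#' CNVR boundary versus overhanging it.
#'
#' @param cnvrs CNVR table (`id`, `chrom`, `start`, `end`).
#' @param genes 1:1-ortholog gene table from [filter_orthologs()].
#' @param min_overlap_bp minimum inclusive overlap (default 1).
#' @return data.frame: `cnvr_id`, `gene_id`, `human_ortholog`, `overlap_bp`,
#'   `contained`.
#' @export
genes_in_cnvrs <- function(cnvrs, genes, min_overlap_bp = 1) {
  if (nrow(cnvrs) == 0 || nrow(genes) == 0) {
    return(data.frame(cnvr_id = character(), gene_id = character(),
                      human_ortholog = character(), overlap_bp = numeric(),
                      contained = logical(), stringsAsFactors = FALSE))
  }
  hits <- find_interval_overlaps(genes, cnvrs, minoverlap = min_overlap_bp)
  gi <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  ov <- pmin(genes$end[gi], cnvrs$end[ci]) -
    pmax(genes$start[gi], cnvrs$start[ci]) + 1
  out <- data.frame(cnvr_id = as.character(cnvrs$id[ci]),
                    gene_id = genes$gene_id[gi],
                    human_ortholog = genes$human_ortholog[gi],
                    overlap_bp = ov,
                    contained = genes$start[gi] >= cnvrs$start[ci] &
                      genes$end[gi] <= cnvrs$end[ci],
                    stringsAsFactors = FALSE)
  out <- out[order(suppressWarnings(as.integer(out$cnvr_id)), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dosage-sensitive genes within CNVRs
#'
#' Intersects the CNVR-overlapping gene list with a list of human genes found
#' copy-number stable across many genomes (presumed dosage sensitive): a
#' copy-number change of such a gene in dogs is a candidate for phenotypic or
#' disease relevance. Duplicate (gene, CNVR) pairs are collapsed.
#'
#' @param cnvr_genes output of [genes_in_cnvrs()].
#' @param dosage_genes character vector of human gene ids.
#' @param summaries optional [classify_cnvr_types()] output to attach `type`.
#' @return data.frame: `cnvr_id`, `gene_id`, `human_ortholog` (+ `type`).
#' @export
dosage_sensitive_report <- function(cnvr_genes, dosage_genes,
                                    summaries = NULL) {
  out <- cnvr_genes[cnvr_genes$human_ortholog %in% dosage_genes,
                    c("cnvr_id", "gene_id", "human_ortholog"), drop = FALSE]
  out <- unique(out)
  if (!is.null(summaries)) {
    out$type <- summaries$type[match(out$cnvr_id, summaries$cnvr_id)]
  }
  out <- out[order(suppressWarnings(as.integer(out$cnvr_id)), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
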