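#' Run the full CNVR discovery pipeline
#'
#' Orchestrates every stage in order: (optional) synthetic-cohort simulation
#' or signal loading, GC correction and sample QC, dual-profile CNV calling,
#' per-profile CNVR merging and dual-profile consensus, relaxed-call
#' genotyping with singleton removal and type/size summaries, and breed
#' frequency / single-breed annotation (gene and published-set annotation run
#' when the corresponding inputs are configured). Every intermediate table is
#' written under `out_dir`, and the returned report carries the count ledger
#' of each stage. Re-running with the same config and seed reproduces every
#' output file byte-identically.
#'
#' @param config a [run_config()]; either `config$sim` (synthetic cohort) or
#'   `config$paths$manifest` + `config$paths$signal` + `config$paths$metadata`
#'   must be set.
#' @param out_dir output directory (created if needed).
#' @return invisible list: all stage outputs plus `report` (named counts).
#' @export
run_all <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$sim)) {
      stage <- "simulate"
      cohort <- simulate_cohort(config$sim)
      manifest <- cohort$manifest
      signals <- cohort$signals
      metadata <- cohort$samples
      write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
      write_signal_table(signals, manifest, file.path(out_dir, "signal.tsv"))
      write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
      write_truth_table(cohort$truths, file.path(out_dir, "truth.tsv"))
    } else {
      stage <- "load"
      if (is.null(config$paths$manifest) || is.null(config$paths$signal) ||
          is.null(config$paths$metadata)) {
        .stopf("config must provide either a sim block or manifest/signal/metadata paths")
      }
      manifest <- load_manifest(config$paths$manifest)
      signals <- load_signal_table(config$paths$signal, manifest)
      metadata <- load_metadata(config$paths$metadata)
      for (s in names(signals)) {
        signals[[s]]$breed <-
          metadata$breed[match(s, metadata$sample)]
      }
      cohort <- NULL
    }
    if (length(signals) == 0) .stopf("no samples")

    exclusion <- if (!is.null(config$paths$exclusion)) {
      load_intervals(config$paths$exclusion)
    } else NULL

    stage <- "qc"
    corrected <- lapply(signals, gc_correct_lrr, manifest = manifest)
    pfb <- estimate_pfb(corrected)
    raw_p_all <- do.call(rbind, lapply(corrected, call_sample,
                                       manifest = manifest,
                                       params = config$p_params, pfb = pfb))
    if (is.null(raw_p_all)) raw_p_all <- empty_calls()
    p_counts <- table(factor(raw_p_all$sample, levels = names(signals)))
    reports <- do.call(rbind, lapply(corrected, function(sg) {
      compute_qc(sg, manifest, n_cnvs = p_counts[[sg$sample]],
                 sd_lrr_max = config$sd_lrr_max,
                 wf_abs_max = config$wf_abs_max,
                 max_cnvs_per_sample = config$max_cnvs_per_sample)
    }))
    rownames(reports) <- NULL
    part <- filter_samples(reports)
    utils::write.table(reports, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "call"
    passed_signals <- corrected[part$passed]
    calls <- call_cohort(passed_signals, manifest, config, exclusion,
                         pfb = pfb, raw_p = raw_p_all)
    write_calls(calls$relaxed_q, file.path(out_dir, "calls_relaxed_q.tsv"))
    write_calls(calls$stringent_q, file.path(out_dir, "calls_stringent_q.tsv"))
    write_calls(calls$p, file.path(out_dir, "calls_p.tsv"))

    stage <- "consensus"
    q_cnvrs <- merge_calls_to_cnvrs(calls$stringent_q, source = "Q")
    p_cnvrs <- merge_calls_to_cnvrs(calls$p, source = "P")
    consensus <- consensus_cnvrs(q_cnvrs, p_cnvrs,
                                 config$cross_caller_min_overlap_bp)
    write_cnvrs(q_cnvrs, file.path(out_dir, "cnvrs_q.tsv"))
    write_cnvrs(p_cnvrs, file.path(out_dir, "cnvrs_p.tsv"))
    write_cnvrs(consensus, file.path(out_dir, "cnvrs_consensus.tsv"))

    stage <- "genotype"
    gt <- genotype_samples(consensus, calls$relaxed_q, part$passed)
    write_genotype_matrix(gt$matrix,
                          file.path(out_dir, "genotypes_all.tsv"))
    sing <- remove_singletons(gt$matrix)
    write_genotype_matrix(sing$matrix,
                          file.path(out_dir, "genotypes_final.tsv"))
    lengths_all <- stats::setNames(cnvr_length(consensus),
                                   as.character(consensus$id))
    summaries <- classify_cnvr_types(sing$matrix, lengths = lengths_all)
    sizes <- summarize_sizes(summaries)
    utils::write.table(summaries, file.path(out_dir, "cnvr_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "annotate"
    metadata_passed <- metadata[metadata$sample %in% part$passed, ,
                                drop = FALSE]
    freqs <- breed_frequencies(sing$matrix, metadata_passed)
    utils::write.table(freqs, file.path(out_dir, "breed_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    published <- if (!is.null(config$paths$published)) {
      load_intervals(config$paths$published)
    } else NULL
    final_cnvrs <- consensus[as.character(consensus$id) %in%
                               rownames(sing$matrix), , drop = FALSE]
    sb <- single_breed_cnvrs(freqs, final_cnvrs, published,
                             config$published_min_overlap_bp)
    utils::write.table(sb$raw, file.path(out_dir, "single_breed_raw.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sb$stringent,
                       file.path(out_dir, "single_breed_stringent.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    report <- c(
      samples_in = length(signals),
      samples_passed = length(part$passed),
      samples_failed = length(part$failed),
      relaxed_q_calls = nrow(calls$relaxed_q),
      stringent_q_calls = nrow(calls$stringent_q),
      p_calls = nrow(calls$p),
      q_cnvrs = nrow(q_cnvrs),
      p_cnvrs = nrow(p_cnvrs),
      consensus_cnvrs = nrow(consensus),
      singletons = length(sing$singletons),
      final_cnvrs = nrow(sing$matrix),
      single_breed_raw = nrow(sb$raw),
      single_breed_stringent = nrow(sb$stringent)
    )
    utils::write.table(
      data.frame(key = names(report), value = as.numeric(report)),
      file.path(out_dir, "report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(cohort = cohort, manifest = manifest, qc = part, reports = reports,
         calls = calls, q_cnvrs = q_cnvrs, p_cnvrs = p_cnvrs,
         consensus = consensus, genotypes = gt, final = sing,
         summaries = summaries, sizes = sizes, breed_frequencies = freqs,
         single_breed = sb, report = report)
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}
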