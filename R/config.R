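#' Pipeline run configuration
#'
#' Bundles every threshold of the discovery/consensus/genotyping pipeline
#' together with input file paths. Defaults are the standard settings for
#' CanineHD-style CNV screens:
#'
#' * `sd_lrr_max = 0.25` — samples with a Log R ratio standard deviation at or
#'   above this fail QC;
#' * `wf_abs_max = 0.04` — samples with |waviness factor| above this fail QC;
#' * `max_cnvs_per_sample = 40` — samples with this many raw P-profile calls
#'   *or more* fail QC;
#' * `min_snps_per_cnv = 5` — calls spanning fewer SNPs are discarded;
#' * `lbf_relaxed = 10`, `lbf_stringent = 30` — Log Bayes factor thresholds for
#'   the relaxed (genotyping) and stringent (discovery) Q-profile call lists;
#' * `cross_caller_min_overlap_bp = 10000` — minimum inclusive overlap between
#'   Q- and P-profile CNVRs for a Q CNVR to enter the consensus list;
#' * `published_min_overlap_bp = 10000` — same rule against published CNVR sets;
#' * `gene_min_overlap_bp = 1` — minimum gene/CNVR overlap;
#' * `freq_strata = c(0.05, 0.01)` — cohort-frequency strata boundaries.
#'
#' @param manifest,signal,metadata,exclusion,published,genes,dosage optional
#'   input file paths (NULL when the corresponding stage is fed in-memory
#'   objects or synthetic data).
#' @param sd_lrr_max,wf_abs_max,max_cnvs_per_sample,min_snps_per_cnv numeric QC
#'   and call-filter thresholds.
#' @param lbf_relaxed,lbf_stringent Log Bayes factor thresholds (natural log).
#' @param cross_caller_min_overlap_bp,published_min_overlap_bp,gene_min_overlap_bp
#'   inclusive overlap thresholds in bp.
#' @param freq_strata numeric vector of descending frequency boundaries.
#' @param seed integer random seed used for any stochastic stage.
#' @param sim a [sim_config()] block for the synthetic-cohort stage, or NULL.
#' @param q_params,p_params HMM parameter blocks, see [hmm_params()].
#' @return object of class `cnvr_run_config`.
#' @export
run_config <- function(manifest = NULL, signal = NULL, metadata = NULL,
                       exclusion = NULL, published = NULL, genes = NULL,
                       dosage = NULL,
                       sd_lrr_max = 0.25, wf_abs_max = 0.04,
                       max_cnvs_per_sample = 40, min_snps_per_cnv = 5,
                       lbf_relaxed = 10, lbf_stringent = 30,
                       cross_caller_min_overlap_bp = 10000,
                       published_min_overlap_bp = 10000,
                       gene_min_overlap_bp = 1,
                       freq_strata = c(0.05, 0.01),
                       seed = 1L,
                       sim = NULL,
                       q_params = hmm_params("Q"),
                       p_params = hmm_params("P")) {
  cfg <- structure(list(
    paths = list(manifest = manifest, signal = signal, metadata = metadata,
                 exclusion = exclusion, published = published, genes = genes,
                 dosage = dosage),
    sd_lrr_max = sd_lrr_max, wf_abs_max = wf_abs_max,
    max_cnvs_per_sample = max_cnvs_per_sample,
    min_snps_per_cnv = min_snps_per_cnv,
    lbf_relaxed = lbf_relaxed, lbf_stringent = lbf_stringent,
    cross_caller_min_overlap_bp = cross_caller_min_overlap_bp,
    published_min_overlap_bp = published_min_overlap_bp,
    gene_min_overlap_bp = gene_min_overlap_bp,
    freq_strata = freq_strata,
    seed = as.integer(seed),
    sim = sim,
    q_params = q_params, p_params = p_params
  ), class = "cnvr_run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param cfg a `cnvr_run_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_run_config <- function(cfg) {
  thr <- c(sd_lrr_max = cfg$sd_lrr_max, wf_abs_max = cfg$wf_abs_max,
           max_cnvs_per_sample = cfg$max_cnvs_per_sample,
           min_snps_per_cnv = cfg$min_snps_per_cnv,
           lbf_relaxed = cfg$lbf_relaxed, lbf_stringent = cfg$lbf_stringent,
           cross_caller_min_overlap_bp = cfg$cross_caller_min_overlap_bp,
           published_min_overlap_bp = cfg$published_min_overlap_bp,
           gene_min_overlap_bp = cfg$gene_min_overlap_bp)
  bad <- names(thr)[!is.finite(thr) | thr <= 0]
  if (length(bad) > 0) .stopf("threshold not strictly positive: %s", bad[1])
  if (cfg$lbf_stringent < cfg$lbf_relaxed) {
    .stopf("lbf_stringent (%s) must be >= lbf_relaxed (%s)",
           cfg$lbf_stringent, cfg$lbf_relaxed)
  }
  if (any(cfg$freq_strata <= 0 | cfg$freq_strata >= 1)) {
    .stopf("freq_strata must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed as
#' numbers where possible, otherwise kept as strings. Recognised keys are the
#' arguments of [run_config()]; unknown keys are an error. Path keys are
#' `manifest`, `signal`, `metadata`, `exclusion`, `published`, `genes`,
#' `dosage`.
#'
#' @param path configuration file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a `cnvr_run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) .stopf("malformed config line: %s", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2]]] <- if (!is.na(num)) num else val
  }
  kv[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0) .stopf("unknown config key: %s", unknown[1])
  do.call(run_config, kv)
}
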