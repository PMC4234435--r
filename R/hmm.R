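#' Five-state HMM parameters
#'
#' Parameter block for the segmentation engine. The engine is an explicit
#' STAND-IN for the two external callers used in published CanineHD CNV
#' screens (QuantiSNP and PennCNV): one HMM run under two parameter profiles,
#' `"Q"` and `"P"`, so that the dual-caller consensus stage is exercised with
#' realistic partial discordance between profiles. It does not reproduce
#' either program's internal likelihoods; thresholds are honoured
#' structurally, not numerically.
#'
#' States are copy numbers 0–4 with Gaussian LRR emissions (means from
#' [lrr_state_means()], sd 0.2 for states 1–4 and 1.0 for the diffuse
#' homozygous-deletion state) and BAF emissions from the genotype-cluster
#' mixture (cluster centres `k/state` weighted binomially in the SNP's
#' population B-allele frequency) plus a 1% uniform outlier component.
#' Transitions are distance-dependent: from state `i`, probability
#' `theta(d) * pi[j] / (1 - pi[i])` to each `j != i` and the remainder
#' (`1 - theta(d)`) to self, with `theta(d) = theta_max * (1 - exp(-d / L))`,
#' `d` the bp gap to the next SNP and `L = 2` Mb. Priors are diploid-heavy
#' (`pi[2] = 0.995`, remainder split evenly). No EM re-estimation is
#' performed; parameters are fixed.
#'
#' @param profile `"Q"` (jump probability 0.005) or `"P"` (0.01).
#' @param mu,sigma LRR state means and sds (states 0..4).
#' @param baf_sd BAF cluster noise sd.
#' @param baf_outlier uniform outlier mixture weight for BAF.
#' @param L transition distance scale in bp.
#' @param theta_max maximum jump probability, in (0, 0.5).
#' @param pi state priors (must sum to 1).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(profile = c("Q", "P"),
                       mu = lrr_state_means(),
                       sigma = c(1.0, 0.2, 0.2, 0.2, 0.2),
                       baf_sd = 0.03,
                       baf_outlier = 0.01,
                       L = 2e6,
                       theta_max = NULL,
                       pi = c(rep(0.005 / 4, 2), 0.995, rep(0.005 / 4, 2))) {
  profile <- match.arg(profile)
  if (is.null(theta_max)) theta_max <- if (profile == "Q") 0.005 else 0.01
  if (abs(sum(pi) - 1) > 1e-8) .stopf("state priors must sum to 1")
  if (L <= 0) .stopf("L must be positive")
  if (theta_max <= 0 || theta_max >= 0.5) .stopf("theta_max must be in (0, 0.5)")
  structure(list(profile = profile, mu = unname(mu), sigma = unname(sigma),
                 baf_sd = baf_sd, baf_outlier = baf_outlier, L = L,
                 theta_max = theta_max, pi = unname(pi)),
            class = "hmm_params")
}

# state preference on score ties: smallest copy-number change first,
# then the lower state; indices are 1..5 for copy states 0..4
.STATE_PREF <- c(3L, 2L, 4L, 1L, 5L)

#' Estimate population B-allele frequencies from a cohort
#'
#' Under Hardy-Weinberg diploidy the expected BAF at a SNP equals its
#' population B-allele frequency, so the per-SNP mean BAF across samples is
#' used, clipped to \[0.05, 0.95\]. Mirrors the compile-PFB step of
#' population-based SNP-array CNV callers.
#'
#' @param signals named list of `sample_signal`.
#' @return numeric vector of per-SNP frequencies.
#' @export
estimate_pfb <- function(signals) {
  baf <- vapply(signals, function(s) s$baf, numeric(length(signals[[1]]$baf)))
  p <- rowMeans(baf, na.rm = TRUE)
  p[is.nan(p)] <- 0.5
  pmin(0.95, pmax(0.05, p))
}

#' Per-SNP emission log-likelihoods
#'
#' Returns the `n x 5` matrix of `log p(lrr | state) + log p(baf | state)`.
#' Missing LRR or BAF values contribute zero to the corresponding term.
#'
#' @param lrr,baf aligned numeric vectors (NA = missing).
#' @param pfb per-SNP population B-allele frequencies.
#' @param params an [hmm_params()].
#' @return matrix, columns = copy states 0..4.
#' @export
hmm_emissions <- function(lrr, baf, pfb, params) {
  n <- length(lrr)
  E <- matrix(0, n, 5)
  for (c in 0:4) {
    j <- c + 1L
    e_lrr <- stats::dnorm(lrr, params$mu[j], params$sigma[j], log = TRUE)
    e_lrr[is.na(e_lrr)] <- 0
    if (c == 0) {
      dens <- rep(1, n)  # uniform BAF under copy 0
    } else {
      dens <- numeric(n)
      for (k in 0:c) {
        dens <- dens + stats::dbinom(k, c, pfb) *
          stats::dnorm(baf, k / c, params$baf_sd)
      }
    }
    e_baf <- log((1 - params$baf_outlier) * dens + params$baf_outlier)
    e_baf[is.na(baf)] <- 0
    E[, j] <- e_lrr + e_baf
  }
  E
}

#' Distance-dependent transition matrix
#'
#' @param d bp gap to the next SNP.
#' @param params an [hmm_params()].
#' @return 5 x 5 row-stochastic matrix.
#' @export
hmm_transition <- function(d, params) {
  theta <- params$theta_max * (1 - exp(-d / params$L))
  A <- theta * matrix(params$pi, 5, 5, byrow = TRUE) /
    (1 - params$pi)  # recycles 1/(1-pi[i]) down rows
  diag(A) <- 1 - theta
  A
}

.viterbi_chrom <- function(E, pos, params) {
  n <- nrow(E)
  pref <- .STATE_PREF
  lpi <- log(params$pi)
  # off-diagonal structure of log A, up to the additive log(theta) term
  logB <- log(matrix(params$pi, 5, 5, byrow = TRUE) / (1 - params$pi))
  V <- lpi + E[1, ]
  if (n == 1) return(pref[which.max(V[pref])] - 1L)
  ptr <- matrix(0L, n, 5)
  gaps <- diff(pos)
  thetas <- params$theta_max * (1 - exp(-gaps / params$L))
  lthetas <- log(thetas)
  ldiag <- log1p(-thetas)
  for (t in 2:n) {
    logA <- logB + lthetas[t - 1L]
    diag(logA) <- ldiag[t - 1L]
    M <- logA + V          # adds V[i] to row i
    M2 <- M[pref, ]
    best <- max.col(t(M2), ties.method = "first")
    V <- E[t, ] + M2[cbind(best, 1:5)]
    ptr[t, ] <- pref[best]
  }
  path <- integer(n)
  path[n] <- pref[which.max(V[pref])]
  for (t in n:2) path[t - 1L] <- ptr[t, path[t]]
  path - 1L  # copy states 0..4
}

#' Viterbi segmentation of one sample
#'
#' Computes the maximum-a-posteriori copy-state path per chromosome under the
#' five-state model of [hmm_params()]. Score ties are broken deterministically
#' towards the smaller copy-number change (preference 2, 1, 3, 0, 4).
#'
#' @param signal corrected `sample_signal`.
#' @param manifest manifest data.frame (sorted; unsorted input is an error).
#' @param params an [hmm_params()].
#' @param pfb per-SNP population B-allele frequencies.
#' @return integer vector of copy states (0..4) aligned to the manifest.
#' @export
viterbi_segment <- function(signal, manifest, params, pfb) {
  validate_manifest(manifest)
  E <- hmm_emissions(signal$lrr, signal$baf, pfb, params)
  path <- integer(nrow(manifest))
  for (ch in unique(manifest$chrom)) {
    i <- which(manifest$chrom == ch)
    path[i] <- .viterbi_chrom(E[i, , drop = FALSE], manifest$pos[i], params)
  }
  path
}

#' Extract CNV calls from a state path
#'
#' Maximal runs of a constant non-diploid state become calls. The Log Bayes
#' factor of a call is the natural-log emission likelihood ratio summed over
#' its SNPs, `sum(log p(lrr,baf | state) - log p(lrr,baf | state 2))`; the
#' interval runs from the first to the last SNP of the run. No filtering is
#' applied here (single-SNP calls are emitted and filtered later).
#'
#' @param path state path from [viterbi_segment()].
#' @param signal the segmented `sample_signal`.
#' @param manifest manifest data.frame.
#' @param params an [hmm_params()].
#' @param pfb per-SNP population B-allele frequencies.
#' @return data.frame: `sample`, `chrom`, `start`, `end`, `copy_state`,
#'   `n_snps`, `lbf`, `profile`.
#' @export
extract_calls <- function(path, signal, manifest, params, pfb) {
  E <- hmm_emissions(signal$lrr, signal$baf, pfb, params)
  lbf_snp <- E - E[, 3]  # per-SNP log ratio vs diploid, per state
  recs <- list()
  for (ch in unique(manifest$chrom)) {
    i <- which(manifest$chrom == ch)
    r <- rle(path[i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != 2L)) {
      idx <- i[starts[k]:ends[k]]
      st <- r$values[k]
      recs[[length(recs) + 1L]] <- data.frame(
        sample = signal$sample, chrom = ch,
        start = manifest$pos[idx[1]], end = manifest$pos[idx[length(idx)]],
        copy_state = st, n_snps = length(idx),
        lbf = sum(lbf_snp[idx, st + 1L]),
        profile = params$profile, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty_calls())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' @rdname extract_calls
#' @export
empty_calls <- function() {
  data.frame(sample = character(), chrom = character(), start = numeric(),
             end = numeric(), copy_state = integer(), n_snps = integer(),
             lbf = numeric(), profile = character(), stringsAsFactors = FALSE)
}

#' Call one sample under one profile
#'
#' @inheritParams viterbi_segment
#' @return raw (unfiltered) call data.frame.
#' @export
call_sample <- function(signal, manifest, params, pfb) {
  path <- viterbi_segment(signal, manifest, params, pfb)
  extract_calls(path, signal, manifest, params, pfb)
}

#' Filter a call table
#'
#' Applies, in order: the minimum SNP-span rule (calls with fewer than
#' `min_snps` SNPs are dropped), removal of calls overlapping (>= 1 bp) any
#' exclusion region, and — when `lbf_threshold` is non-NULL — removal of calls
#' with `lbf < lbf_threshold`. Exclusion regions encode noisy genomic regions
#' that would otherwise produce fragmented spurious calls.
#'
#' @param calls call data.frame (one profile).
#' @param min_snps minimum SNPs per call (default 5).
#' @param exclusion_regions interval table or NULL.
#' @param lbf_threshold numeric threshold (applied as `lbf >= threshold`), or
#'   NULL to skip LBF filtering (the P-profile convention).
#' @param verbose log filter counts.
#' @return filtered call data.frame, sorted by (chrom, start, sample).
#' @export
filter_calls <- function(calls, min_snps = 5, exclusion_regions = NULL,
                         lbf_threshold = NULL, verbose = FALSE) {
  n0 <- nrow(calls)
  keep <- calls$n_snps >= min_snps
  .log_filter(sprintf("calls with < %d SNPs", min_snps),
              sum(!keep), sum(keep), verbose)
  calls <- calls[keep, , drop = FALSE]
  if (!is.null(exclusion_regions) && nrow(exclusion_regions) > 0 &&
      nrow(calls) > 0) {
    hits <- find_interval_overlaps(calls, exclusion_regions)
    drop <- unique(S4Vectors::queryHits(hits))
    .log_filter("calls in excluded regions", length(drop),
                nrow(calls) - length(drop), verbose)
    if (length(drop) > 0) calls <- calls[-drop, , drop = FALSE]
  }
  if (!is.null(lbf_threshold)) {
    keep <- calls$lbf >= lbf_threshold
    .log_filter(sprintf("calls with LBF < %s", lbf_threshold),
                sum(!keep), sum(keep), verbose)
    calls <- calls[keep, , drop = FALSE]
  }
  calls <- calls[order(suppressWarnings(as.integer(calls$chrom)), calls$start,
                       calls$sample), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call a cohort under both profiles
#'
#' Runs the segmentation engine for every (QC-passed) sample under the Q and P
#' profiles and produces the three standard call tables: the relaxed Q list
#' (`lbf >= lbf_relaxed`, used downstream for genotyping), the stringent Q
#' list (`lbf >= lbf_stringent`, used for discovery; always a subset of the
#' relaxed list), and the P list (no LBF filter — the LBF thresholds are a
#' Q-profile concept). All three receive the SNP-span and exclusion-region
#' filters.
#'
#' @param signals named list of corrected `sample_signal` (QC-passed only).
#' @param manifest manifest data.frame.
#' @param config a [run_config()].
#' @param exclusion_regions interval table or NULL.
#' @param pfb per-SNP population frequencies; estimated from `signals` when
#'   NULL.
#' @param raw_p optional precomputed raw P-profile calls (e.g. from the QC
#'   stage) to avoid a second P pass; must cover exactly these samples.
#' @return list: `relaxed_q`, `stringent_q`, `p`, `raw_q`, `raw_p`.
#' @export
call_cohort <- function(signals, manifest, config = run_config(),
                        exclusion_regions = NULL, pfb = NULL, raw_p = NULL) {
  if (length(signals) == 0) {
    e <- empty_calls()
    return(list(relaxed_q = e, stringent_q = e, p = e, raw_q = e, raw_p = e))
  }
  if (is.null(pfb)) pfb <- estimate_pfb(signals)
  raw_q <- do.call(rbind, lapply(signals, call_sample, manifest = manifest,
                                 params = config$q_params, pfb = pfb))
  if (is.null(raw_p)) {
    raw_p <- do.call(rbind, lapply(signals, call_sample, manifest = manifest,
                                   params = config$p_params, pfb = pfb))
  } else {
    raw_p <- raw_p[raw_p$sample %in% names(signals), , drop = FALSE]
  }
  if (is.null(raw_q)) raw_q <- empty_calls()
  if (is.null(raw_p)) raw_p <- empty_calls()
  rownames(raw_q) <- rownames(raw_p) <- NULL
  list(
    relaxed_q = filter_calls(raw_q, config$min_snps_per_cnv,
                             exclusion_regions, config$lbf_relaxed),
    stringent_q = filter_calls(raw_q, config$min_snps_per_cnv,
                               exclusion_regions, config$lbf_stringent),
    p = filter_calls(raw_p, config$min_snps_per_cnv, exclusion_regions, NULL),
    raw_q = raw_q, raw_p = raw_p
  )
}
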