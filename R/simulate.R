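#' Synthetic cohort configuration
#'
#' Describes a multi-breed SNP-array cohort with planted copy number variants.
#' Defaults emulate a CanineHD-style screen scaled to desk size: 5 chromosomes
#' of 40 Mb with ~13 kb mean SNP spacing (~15,000 SNPs), 5 breeds of 12
#' samples, 20 planted variants (8 shared across breeds, 8 single-breed,
#' 4 singletons) with copy states in \{0,1,3,4\} and spans of at least 8 SNPs,
#' per-sample LRR noise sd 0.15 with a 5% minority of bad samples at sd 0.35,
#' and BAF noise sd 0.03. Single-breed carrier frequencies default to the
#' 0.17–0.42 range observed for breed-specific CNVRs on this array class.
#'
#' @param n_chroms number of autosomes to simulate.
#' @param chrom_length_bp chromosome length in bp.
#' @param mean_snp_spacing_bp target mean inter-SNP distance (jittered).
#' @param breeds named integer vector: samples per breed.
#' @param n_shared,n_single_breed,n_singleton planted variant counts per
#'   category.
#' @param span_snps integer range (min, max) of SNPs spanned per variant.
#' @param states candidate copy states for planted variants.
#' @param single_breed_freq range of within-breed carrier frequencies for
#'   single-breed variants.
#' @param shared_freq range of within-breed carrier frequencies for shared
#'   variants (applied in each of 2–3 breeds).
#' @param lrr_sd baseline per-sample LRR noise sd.
#' @param bad_sample_frac fraction of samples simulated as bad quality.
#' @param bad_lrr_sd LRR noise sd for bad samples (>= 0.30 so they fail QC).
#' @param baf_sd BAF cluster noise sd.
#' @param gc_wave_amplitude amplitude of GC-correlated LRR waviness (0 = off).
#' @param noisy_regions optional interval table of regions with inflated
#'   variance (exercises the exclusion-region filter).
#' @param noisy_region_sd extra LRR noise sd inside `noisy_regions`.
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 5,
                       chrom_length_bp = 40e6,
                       mean_snp_spacing_bp = 13000,
                       breeds = c(Beagle = 12L, Boxer = 12L, Collie = 12L,
                                  Poodle = 12L, Spitz = 12L),
                       n_shared = 8, n_single_breed = 8, n_singleton = 4,
                       span_snps = c(8L, 30L),
                       states = c(0L, 1L, 3L, 4L),
                       single_breed_freq = c(0.17, 0.42),
                       shared_freq = c(0.15, 0.40),
                       lrr_sd = 0.15,
                       bad_sample_frac = 0.05,
                       bad_lrr_sd = 0.35,
                       baf_sd = 0.03,
                       gc_wave_amplitude = 0,
                       noisy_regions = NULL,
                       noisy_region_sd = 0.5,
                       seed) {
  if (missing(seed) || is.null(seed)) .stopf("sim_config requires a seed")
  if (any(span_snps < 1)) .stopf("variant spans must be >= 1 SNP")
  if (any(c(single_breed_freq, shared_freq) < 0) ||
      any(c(single_breed_freq, shared_freq) > 1)) {
    .stopf("carrier frequencies must lie in [0,1]")
  }
  if (is.null(names(breeds)) || any(!nzchar(names(breeds)))) {
    .stopf("breeds must be a named vector")
  }
  structure(list(
    n_chroms = n_chroms, chrom_length_bp = chrom_length_bp,
    mean_snp_spacing_bp = mean_snp_spacing_bp, breeds = breeds,
    n_shared = n_shared, n_single_breed = n_single_breed,
    n_singleton = n_singleton, span_snps = as.integer(span_snps),
    states = as.integer(states),
    single_breed_freq = single_breed_freq, shared_freq = shared_freq,
    lrr_sd = lrr_sd, bad_sample_frac = bad_sample_frac,
    bad_lrr_sd = bad_lrr_sd, baf_sd = baf_sd,
    gc_wave_amplitude = gc_wave_amplitude,
    noisy_regions = noisy_regions, noisy_region_sd = noisy_region_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Canonical five-state LRR means; c2 (diploid) is the zero baseline and the
# c1/c3 asymmetry reflects the log2 response of one-copy loss vs gain.
.LRR_MU <- c(`0` = -3.5, `1` = -0.66, `2` = 0, `3` = 0.40, `4` = 0.68)

#' LRR state means used by both the simulator and the caller defaults
#' @return named numeric vector for copy states 0..4.
#' @export
lrr_state_means <- function() .LRR_MU

#' Generate a synthetic SNP manifest
#'
#' SNP positions are laid down per chromosome with exponentially jittered
#' spacing of the configured mean; GC fractions follow a smooth autocorrelated
#' profile in \[0.2, 0.8\].
#'
#' @param cfg a [sim_config()].
#' @return manifest data.frame (`snp_id`, `chrom`, `pos`, `gc`).
#' @export
generate_manifest <- function(cfg) {
  if (cfg$mean_snp_spacing_bp >= cfg$chrom_length_bp) {
    .stopf("mean SNP spacing (%s) exceeds chromosome length (%s)",
           cfg$mean_snp_spacing_bp, cfg$chrom_length_bp)
  }
  set.seed(cfg$seed)
  pieces <- vector("list", cfg$n_chroms)
  for (ch in seq_len(cfg$n_chroms)) {
    n_guess <- ceiling(1.5 * cfg$chrom_length_bp / cfg$mean_snp_spacing_bp)
    gaps <- pmax(50, round(stats::rexp(n_guess, 1 / cfg$mean_snp_spacing_bp)))
    pos <- cumsum(gaps)
    pos <- pos[pos <= cfg$chrom_length_bp]
    pos <- unique(pos)
    n <- length(pos)
    # smooth GC: AR(1) profile squashed into [0.2, 0.8]
    z <- as.numeric(stats::filter(stats::rnorm(n), 0.995, "recursive"))
    z <- (z - mean(z)) / stats::sd(z)
    gc <- 0.2 + 0.6 * stats::pnorm(z)
    pieces[[ch]] <- data.frame(
      snp_id = sprintf("snp_%d_%07d", ch, seq_len(n)),
      chrom = as.character(ch), pos = pos, gc = gc,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL
  validate_manifest(df)
  df
}

#' Plant ground-truth CNVs on a manifest
#'
#' Places non-overlapping variants (shared across 2–3 breeds, single-breed, or
#' singleton), snapped to SNP positions: each interval runs from the first to
#' the last spanned SNP. Carrier counts follow the configured within-breed
#' frequencies (`round(freq * n_breed)`, at least 1).
#'
#' @param cfg a [sim_config()].
#' @param manifest manifest from [generate_manifest()].
#' @return data.frame of truth records: `truth_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `copy_state`, `category`, `breeds`, `carriers`
#'   (comma-separated sample ids); also carries the cohort sample table as
#'   attribute `samples`.
#' @export
plant_truth_cnvs <- function(cfg, manifest) {
  if (nrow(manifest) == 0) .stopf("empty manifest")
  set.seed(cfg$seed + 1L)
  samples <- data.frame(
    sample = unlist(lapply(names(cfg$breeds), function(b)
      sprintf("%s_%02d", b, seq_len(cfg$breeds[[b]])))),
    breed = rep(names(cfg$breeds), cfg$breeds),
    stringsAsFactors = FALSE)

  n_total <- cfg$n_shared + cfg$n_single_breed + cfg$n_singleton
  if (n_total == 0) {
    out <- data.frame(truth_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_snps = integer(),
                      copy_state = integer(), category = character(),
                      breeds = character(), carriers = character(),
                      stringsAsFactors = FALSE)
    attr(out, "samples") <- samples
    return(out)
  }
  categories <- c(rep("shared", cfg$n_shared),
                  rep("single_breed", cfg$n_single_breed),
                  rep("singleton", cfg$n_singleton))

  used <- list()  # per chrom: matrix of occupied SNP index ranges
  recs <- vector("list", n_total)
  chroms <- unique(manifest$chrom)
  max_tries <- 200L
  for (v in seq_len(n_total)) {
    span <- .sample1(seq(cfg$span_snps[1], cfg$span_snps[2]))
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- .sample1(chroms)
      mi <- which(manifest$chrom == ch)
      if (length(mi) < span + 4) next
      # keep 2 SNPs of diploid flank inside the chromosome
      i0 <- .sample1(seq(3, length(mi) - span - 1))
      lo <- i0 - 2L
      hi <- i0 + span + 1L  # flank-padded occupancy to keep variants separated
      occ <- used[[ch]]
      clash <- !is.null(occ) && any(occ[, 1] <= hi & occ[, 2] >= lo)
      if (clash) next
      if (!is.null(cfg$noisy_regions)) {
        iv <- cfg$noisy_regions
        s <- manifest$pos[mi[i0]]; e <- manifest$pos[mi[i0 + span - 1L]]
        in_noisy <- any(iv$chrom == ch & iv$start <= e & iv$end >= s)
        if (in_noisy) next
      }
      used[[ch]] <- rbind(occ, c(lo, hi))
      snp_idx <- mi[i0:(i0 + span - 1L)]
      state <- .sample1(cfg$states)
      cat_v <- categories[v]
      if (cat_v == "singleton") {
        carriers <- .sample1(samples$sample)
      } else if (cat_v == "single_breed") {
        b <- .sample1(names(cfg$breeds))
        f <- stats::runif(1, cfg$single_breed_freq[1], cfg$single_breed_freq[2])
        k <- max(2L, round(f * cfg$breeds[[b]]))
        carriers <- .sample_n(samples$sample[samples$breed == b], k)
      } else {
        n_b <- min(length(cfg$breeds), .sample1(2:3))
        bs <- sample(names(cfg$breeds), n_b)
        carriers <- unlist(lapply(bs, function(b) {
          f <- stats::runif(1, cfg$shared_freq[1], cfg$shared_freq[2])
          k <- max(1L, round(f * cfg$breeds[[b]]))
          .sample_n(samples$sample[samples$breed == b], k)
        }))
      }
      recs[[v]] <- data.frame(
        truth_id = sprintf("tv%02d", v), chrom = ch,
        start = manifest$pos[snp_idx[1]],
        end = manifest$pos[snp_idx[length(snp_idx)]],
        n_snps = span, copy_state = state, category = cat_v,
        breeds = paste(sort(unique(
          samples$breed[samples$sample %in% carriers])), collapse = ","),
        carriers = paste(sort(carriers), collapse = ","),
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      .stopf(paste0("could not place truth variant %d without overlap after %d",
                    " tries; use fewer or shorter variants"), v, max_tries)
    }
  }
  out <- do.call(rbind, recs)
  out <- out[order(suppressWarnings(as.integer(out$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Carrier list of a truth record
#' @param truth one row of the truth table (or the table plus an index).
#' @return character vector of sample ids.
#' @export
truth_carriers <- function(truth) {
  strsplit(truth$carriers, ",", fixed = TRUE)[[1]]
}

# BAF emission mixture for copy state c at population B-allele frequency p:
# cluster centres k/c for k = 0..c, weights Binomial(c, p); copy 0 is uniform.
.baf_cluster_centres <- function(state) {
  if (state == 0) return(numeric(0))
  (0:state) / state
}

#' Simulate LRR/BAF signals for a cohort
#'
#' For every sample and SNP, `LRR = mu[state] + wave(gc) + N(0, sd_sample)`
#' with the five-state means of [lrr_state_means()]; BAF is drawn from the
#' genotype-cluster mixture of the SNP's copy state (cluster centres `k/state`
#' weighted binomially in the SNP's population B-allele frequency, Gaussian
#' noise, clipped to \[0,1\]; copy 0 is uniform). `wave(gc)` is
#' `amplitude * (gc - mean(gc)) / sd(gc)`.
#'
#' @param manifest manifest data.frame.
#' @param truths truth table from [plant_truth_cnvs()].
#' @param cfg a [sim_config()].
#' @return named list of [sample_signal()] objects with attributes `pfb`
#'   (per-SNP population B-allele frequency), `bad_samples` (ids simulated at
#'   `bad_lrr_sd`), and `samples` (sample/breed table).
#' @export
simulate_signals <- function(manifest, truths, cfg) {
  samples <- attr(truths, "samples")
  if (is.null(samples)) .stopf("truth table lacks its sample attribute")
  set.seed(cfg$seed + 2L)
  n <- nrow(manifest)
  pfb <- stats::runif(n, 0.05, 0.95)
  wave <- if (cfg$gc_wave_amplitude != 0 && stats::sd(manifest$gc) > 0) {
    cfg$gc_wave_amplitude * (manifest$gc - mean(manifest$gc)) /
      stats::sd(manifest$gc)
  } else rep(0, n)

  n_bad <- round(cfg$bad_sample_frac * nrow(samples))
  bad <- if (n_bad > 0) sample(samples$sample, n_bad) else character(0)

  # per-sample copy-state vector from the truth table
  state_of <- function(sid) {
    st <- rep(2L, n)
    for (r in seq_len(nrow(truths))) {
      if (sid %in% truth_carriers(truths[r, ])) {
        inside <- manifest$chrom == truths$chrom[r] &
          manifest$pos >= truths$start[r] & manifest$pos <= truths$end[r]
        st[inside] <- truths$copy_state[r]
      }
    }
    st
  }

  noisy_mask <- rep(FALSE, n)
  if (!is.null(cfg$noisy_regions)) {
    for (r in seq_len(nrow(cfg$noisy_regions))) {
      iv <- cfg$noisy_regions[r, ]
      noisy_mask <- noisy_mask | (manifest$chrom == normalize_chrom(iv$chrom) &
                                    manifest$pos >= iv$start &
                                    manifest$pos <= iv$end)
    }
  }

  out <- vector("list", nrow(samples))
  names(out) <- samples$sample
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample[i]
    st <- state_of(sid)
    sd_i <- if (sid %in% bad) cfg$bad_lrr_sd else cfg$lrr_sd
    sd_vec <- rep(sd_i, n)
    sd_vec[noisy_mask] <- sqrt(sd_i^2 + cfg$noisy_region_sd^2)
    lrr <- .LRR_MU[as.character(st)] + wave + stats::rnorm(n, 0, sd_vec)
    baf <- numeric(n)
    for (s in unique(st)) {
      j <- which(st == s)
      if (s == 0) {
        baf[j] <- stats::runif(length(j))
      } else {
        k <- stats::rbinom(length(j), s, pfb[j])
        baf[j] <- k / s + stats::rnorm(length(j), 0, cfg$baf_sd)
      }
    }
    baf <- pmin(1, pmax(0, baf))
    out[[i]] <- sample_signal(sid, lrr, baf, breed = samples$breed[i])
  }
  attr(out, "pfb") <- pfb
  attr(out, "bad_samples") <- sort(bad)
  attr(out, "samples") <- samples
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: manifest, planted truths and signals in one call.
#'
#' @param cfg a [sim_config()].
#' @return list with `manifest`, `truths`, `signals`, `samples`, `pfb`,
#'   `bad_samples`.
#' @export
simulate_cohort <- function(cfg) {
  manifest <- generate_manifest(cfg)
  truths <- plant_truth_cnvs(cfg, manifest)
  signals <- simulate_signals(manifest, truths, cfg)
  list(manifest = manifest, truths = truths, signals = signals,
       samples = attr(signals, "samples"), pfb = attr(signals, "pfb"),
       bad_samples = attr(signals, "bad_samples"))
}

#' Write the truth table
#' @param truths truth table.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truths, path) {
  utils::write.table(truths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
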