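#' Bundled reference tables from a published CanineHD dog cohort
#'
#' Small plain-text tables shipped with the package, taken from a published
#' genome-wide CNV screen of a 30-breed dog cohort genotyped on the CanineHD
#' array (351 dogs passing QC):
#'
#' * [caninehd_single_breed_cnvrs()] — the stringent list of 15 single-breed
#'   CNVRs with coordinates, reported lengths, types, breed carrier counts
#'   and overlapping genes;
#' * [caninehd_dosage_genes()] — the 23 copy-number-variable canine genes
#'   whose human orthologs fall in human copy-number-stable (dosage
#'   sensitive) regions, with their CNVRs;
#' * [caninehd_exclusion_regions()] — the three noisy genomic regions
#'   (chr1:13–15.7 Mb, chr15:10.2–13.5 Mb, chr36:16–19.2 Mb, 9.2 Mb in total
#'   by the end − start convention) excluded from CNV calling because of
#'   extensively fragmented segmentation.
#'
#' @name reference_tables
NULL

.extdata <- function(file) {
  system.file("extdata", file, package = "cnvrforge", mustWork = TRUE)
}

#' @rdname reference_tables
#' @return data.frame of 15 single-breed CNVRs.
#' @export
caninehd_single_breed_cnvrs <- function() {
  utils::read.table(.extdata("caninehd_single_breed_cnvrs.tsv"),
                    header = TRUE, sep = "\t", quote = "", fill = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname reference_tables
#' @return data.frame of dosage-sensitive gene / CNVR pairs.
#' @export
caninehd_dosage_genes <- function() {
  utils::read.table(.extdata("caninehd_dosage_sensitive_genes.tsv"),
                    header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname reference_tables
#' @return interval table of the three excluded regions.
#' @export
caninehd_exclusion_regions <- function() {
  load_intervals(.extdata("caninehd_exclusion_regions.tsv"))
}

#' Synthetic reference genotype matrix
#'
#' A deterministic, fully SYNTHETIC stand-in for a population CNVR genotype
#' matrix of a 351-sample, 110-CNVR cohort. It is *constructed*, not
#' measured: carrier counts, copy states and region lengths are laid out so
#' that the matrix is consistent with the summary statistics published for
#' the CanineHD cohort of [reference_tables] — 110 CNVRs of which 38 are
#' singletons; among the remaining 72: 31 pure deletions, 30 pure
#' duplications and 11 mixed del/dupl regions (with ~80% of mixed-region
#' carriers bearing duplications); length strata 14 below 100 kb, 46 between
#' 100 kb and 1 Mb, 12 above 1 Mb; overall median length 194,559 bp with
#' per-type medians 154,574 (del), 281,565 (dupl) and 447,710 (del/dupl) and
#' a minimum of 38 kb; cohort-frequency strata of 11 regions above 5%, 48 at
#' or above 1% and 24 below 1%. It exists so the genotyping-stage
#' operations (singleton removal, type classification, size summaries) can
#' be exercised at the published cohort's scale; it carries no information
#' about real carriers or coordinates.
#'
#' @param n_samples cohort size (default 351).
#' @return list: `matrix` (110 x n_samples integer genotype matrix, states
#'   0..4), `cnvrs` (data.frame `id`, `chrom`, `start`, `end`, `length`).
#' @export
synthetic_reference_matrix <- function(n_samples = 351) {
  # length layout satisfying the published medians and strata (see docs)
  del_len <- c(seq(38000, 83000, by = 5000),            # 10 below 100 kb
               seq(110000, 150000, by = 10000),          # 5
               154574,                                   # median (16th of 31)
               seq(160000, 180000, by = 5000),           # 5
               seq(250000, 340000, by = 10000))          # 10
  dup_len <- c(seq(60000, 90000, by = 10000),            # 4 below 100 kb
               seq(120000, 190000, by = 10000),          # 8
               210000, 230000,
               281565, 281565,                           # median (15th/16th)
               seq(300000, 600000, by = 50000),          # 7
               seq(1100000, 1700000, by = 100000))       # 7 above 1 Mb
  dd_len <- c(120000, 150000, 194559, 194559,            # overall median pair
              300000, 447710,                            # median (6th of 11)
              seq(1050000, 1250000, by = 50000))         # 5 above 1 Mb
  stopifnot(length(del_len) == 31, length(dup_len) == 30, length(dd_len) == 11)

  type <- c(rep("del", 31), rep("dupl", 30), rep("del/dupl", 11),
            rep(c("del", "dupl"), length.out = 38))      # 38 singletons
  len <- c(del_len, dup_len, dd_len,
           rep(seq(50000, 500000, length.out = 19), 2)[seq_len(38)])

  # carrier counts: 11 regions above 5% (>= 18/351), 37 between 1% and 5%
  # (4..17), 24 below 1% (2..3), then the 38 singletons
  cc <- c(seq(18, 28, length.out = 11),
          rep(4:17, length.out = 37),
          rep(2:3, length.out = 24),
          rep(1, 38))
  carriers <- as.integer(round(cc))

  n_cnvr <- 110L
  chrom <- as.character((seq_len(n_cnvr) - 1L) %% 38L + 1L)
  idx_on_chrom <- stats::ave(seq_len(n_cnvr), chrom, FUN = seq_along)
  start <- 1e6 + (idx_on_chrom - 1) * 5e6
  end <- start + len

  samples <- sprintf("S%03d", seq_len(n_samples))
  m <- matrix(2L, n_cnvr, n_samples,
              dimnames = list(as.character(seq_len(n_cnvr)), samples))
  for (i in seq_len(n_cnvr)) {
    k <- carriers[i]
    who <- ((i * 7 + seq_len(k) - 1L) %% n_samples) + 1L
    g <- switch(type[i],
      "del" = c(0L, rep(1L, k - 1L))[seq_len(k)],
      "dupl" = c(4L, rep(3L, k - 1L))[seq_len(k)],
      "del/dupl" = {
        n_dup <- max(1L, ceiling(0.8 * k))
        n_del <- max(1L, k - n_dup)
        c(rep(3L, k - n_del), rep(1L, n_del))
      })
    m[i, who] <- g
  }
  cnvrs <- data.frame(id = seq_len(n_cnvr), chrom = chrom, start = start,
                      end = end, length = len, stringsAsFactors = FALSE)
  list(matrix = m, cnvrs = cnvrs)
}

#' Synthetic qPCR validation outcome table
#'
#' A deterministic SYNTHETIC stand-in for a qPCR validation campaign over
#' nine CNVRs and 106 sample-locus combinations, consistent with the
#' published validation summary of the CanineHD cohort: 20 combinations
#' carry an array CNV genotype, exactly one false positive (an array carrier
#' read as normal by qPCR, at CNVR 45, whose only tested carrier it is) and
#' one false negative (an array-normal combination read as a deletion). Run
#' through [concordance()] and [validation_rate()] this reproduces the
#' published 98% genotype concordance and 89% (8/9) validation rate by
#' construction of the *inputs*; the percentages themselves are computed by
#' the package's arithmetic.
#'
#' @return data.frame: `sample`, `locus`, `array_class`, `qpcr_class`.
#' @export
synthetic_validation_outcomes <- function() {
  loci <- c("9", "16", "45", "48", "57", "69", "78", "82", "96")
  # tested carriers per locus (total 20); CNVR 45 has a single tested carrier
  n_car <- c(`9` = 3L, `16` = 2L, `45` = 1L, `48` = 2L, `57` = 3L,
             `69` = 2L, `78` = 4L, `82` = 2L, `96` = 1L)
  car_class <- c(`9` = "dup", `16` = "dup", `45` = "del", `48` = "dup",
                 `57` = "dup", `69` = "dup", `78` = "del", `82` = "dup",
                 `96` = "del")
  rows <- list()
  s <- 0L
  for (l in loci) {
    for (j in seq_len(n_car[[l]])) {
      s <- s + 1L
      qp <- if (l == "45") "normal" else car_class[[l]]  # the false positive
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("V%03d", s), locus = l,
        array_class = car_class[[l]], qpcr_class = qp,
        stringsAsFactors = FALSE)
    }
  }
  # 86 array-normal combinations, one of them the false negative
  for (j in seq_len(86L)) {
    s <- s + 1L
    l <- loci[(j - 1L) %% length(loci) + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sprintf("V%03d", s), locus = l,
      array_class = "normal",
      qpcr_class = if (j == 1L) "del" else "normal",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
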