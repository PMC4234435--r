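breed_meta <- function(m) {
  data.frame(sample = colnames(m),
             breed = rep(c("Spitz", "Spaniel"), each = 12),
             stringsAsFactors = FALSE)
}

test_that("breed frequencies use half-up rounding to 2 decimals", {
  m <- matrix(2L, 2, 24,
              dimnames = list(c("78", "47"), sprintf("d%02d", 1:24)))
  m["78", 1:4] <- 1L        # 4/12 Spitz
  m["47", 13:17] <- 1L      # 5/12 Spaniel
  fr <- breed_frequencies(m, breed_meta(m))
  expect_equal(fr$freq[fr$cnvr_id == "78"], 0.33)
  expect_equal(fr$freq[fr$cnvr_id == "47"], 0.42)
  expect_equal(fr$n_screened, c(12L, 12L))
  # breeds with zero affected produce no record
  expect_equal(nrow(fr), 2)
  expect_error(breed_frequencies(m, breed_meta(m)[-1, ]), "without breed")
})

test_that("single-breed status requires carriers from exactly one breed", {
  m <- matrix(2L, 2, 24,
              dimnames = list(c("1", "2"), sprintf("d%02d", 1:24)))
  m["1", c(1, 2)] <- 1L          # Spitz only
  m["2", c(1, 13)] <- 3L         # both breeds
  fr <- breed_frequencies(m, breed_meta(m))
  cnvrs <- data.frame(id = c(1, 2), chrom = "1",
                      start = c(1e6, 5e6), end = c(1.3e6, 5.3e6))
  sb <- single_breed_cnvrs(fr, cnvrs, published = NULL)
  expect_equal(sb$raw$cnvr_id, "1")
  expect_equal(sb$stringent$cnvr_id, "1")
})

test_that("published overlaps in other or unknown breeds remove a CNVR", {
  m <- matrix(2L, 3, 24,
              dimnames = list(c("1", "2", "3"), sprintf("d%02d", 1:24)))
  m[1, 1:2] <- 1L; m[2, 3:4] <- 1L; m[3, 5:6] <- 1L   # all Spitz-only
  fr <- breed_frequencies(m, breed_meta(m))
  cnvrs <- data.frame(id = 1:3, chrom = "1",
                      start = c(1e6, 5e6, 9e6), end = c(1.3e6, 5.3e6, 9.3e6))
  published <- interval_table(
    chrom = c("1", "1", "1"),
    start = c(1e6, 5e6, 9e6), end = c(1.1e6, 5.1e6, 9.1e6),
    breed = c(NA, "Spaniel", "Spitz"))
  sb <- single_breed_cnvrs(fr, cnvrs, published, min_overlap_bp = 10000)
  # unknown breed -> removed; different breed -> removed; same breed -> kept
  expect_equal(sb$stringent$cnvr_id, "3")
  expect_setequal(sb$removed$reason,
                  c("published breed unknown", "published in different breed"))
  # stringent is always a subset of raw
  expect_true(all(sb$stringent$cnvr_id %in% sb$raw$cnvr_id))
  # a sub-threshold overlap (< 10 kb) does not remove
  sb2 <- single_breed_cnvrs(fr, cnvrs, published, min_overlap_bp = 200000)
  expect_equal(nrow(sb2$stringent), 3)
})

test_that("frequency strata are cumulative and partition at 1%", {
  cnvrs <- data.frame(id = 1:6, chrom = "1",
                      start = (1:6) * 1e6, end = (1:6) * 1e6 + 5e4)
  freqs <- setNames(c(0.10, 0.06, 0.02, 0.011, 0.005, 0.003),
                    as.character(1:6))
  published <- interval_table("1", 1e6, 1.2e6)  # overlaps CNVR 1 only
  tab <- stratified_published_overlap(cnvrs, freqs, published,
                                      min_overlap_bp = 10000)
  expect_equal(tab$n, c(6L, 2L, 4L, 2L))
  expect_equal(tab$n[tab$stratum == "gt_0.01"] +
                 tab$n[tab$stratum == "lt_0.01"],
               tab$n[tab$stratum == "all"])
  expect_equal(tab$n_overlap, c(1L, 1L, 1L, 0L))
  # a 9,999 bp overlap does not count
  pub2 <- interval_table("1", 1e6, 1e6 + 9998)
  tab2 <- stratified_published_overlap(cnvrs, freqs, pub2)
  expect_equal(tab2$n_overlap[1], 0L)
  # percentage formatting is half-up: 35/48 -> 73
  expect_equal(round_half_up(100 * 35 / 48), 73)
  expect_equal(round_half_up(100 * 43 / 72), 60)
  expect_equal(round_half_up(100 * 8 / 24), 33)
})

test_that("ortholog filtering applies its four rules in order", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    human_ortholog = c(NA, "H1", "H2", "H2", "H3", "H4"),
    chrom = c("1", "X", "1", "2", "3", "4"),
    start = 1, end = 100, stringsAsFactors = FALSE)
  out <- filter_orthologs(genes)
  # g1 no ortholog, g2 chrX, g3/g4 share a human id -> g5, g6 remain
  expect_setequal(out$gene_id, c("g5", "g6"))
  ledger <- attr(out, "ledger")
  expect_equal(unname(ledger), c(6L, 5L, 4L, 4L, 2L))
  expect_true(all(diff(ledger) <= 0))
  expect_equal(nrow(filter_orthologs(genes[0, ])), 0)
})

test_that("chrX duplicates are removed before uniqueness checks", {
  # a chrX gene sharing a human id with an autosomal gene must not drag the
  # autosomal gene out: X filtering precedes the uniqueness rules
  genes <- data.frame(
    gene_id = c("gX", "gA", "gB"),
    human_ortholog = c("H1", "H1", "H2"),
    chrom = c("X", "5", "6"),
    start = 1, end = 100, stringsAsFactors = FALSE)
  out <- filter_orthologs(genes)
  expect_setequal(out$gene_id, c("gA", "gB"))
  # independent set-algebra oracle for the same rules
  s <- genes[!is.na(genes$human_ortholog), ]
  s <- s[s$chrom %in% as.character(1:38), ]
  s <- s[ave(seq_len(nrow(s)), s$gene_id, FUN = length) == 1, ]
  s <- s[ave(seq_len(nrow(s)), s$human_ortholog, FUN = length) == 1, ]
  expect_setequal(out$gene_id, s$gene_id)
})

test_that("gene overlap uses closed-interval arithmetic with containment", {
  cnvrs <- data.frame(id = 1, chrom = "1", start = 100, end = 300)
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      human_ortholog = c("HA", "HB", "HC"),
                      chrom = "1",
                      start = c(300, 150, 301), end = c(400, 200, 400),
                      stringsAsFactors = FALSE)
  ov <- genes_in_cnvrs(cnvrs, genes)
  expect_setequal(ov$gene_id, c("a", "b"))   # 1 shared base counts; 301 does not
  expect_equal(ov$contained[ov$gene_id == "a"], FALSE)
  expect_equal(ov$contained[ov$gene_id == "b"], TRUE)
  expect_equal(ov$overlap_bp[ov$gene_id == "a"], 1)
})

test_that("dosage-sensitive intersection is duplicate-free and order-stable", {
  cg <- data.frame(cnvr_id = c("2", "1", "1", "1"),
                   gene_id = c("g4", "g1", "g2", "g2"),
                   human_ortholog = c("H4", "H1", "H2", "H2"),
                   overlap_bp = 10, contained = TRUE,
                   stringsAsFactors = FALSE)
  rep1 <- dosage_sensitive_report(cg, c("H2", "H4"))
  expect_equal(rep1$gene_id, c("g2", "g4"))
  expect_equal(nrow(dosage_sensitive_report(cg, character(0))), 0)
  # order independence
  rep2 <- dosage_sensitive_report(cg[c(4, 3, 2, 1), ], c("H4", "H2"))
  expect_equal(rep1, rep2)
})

test_that("the bundled single-breed table behaves as an annotation input", {
  tab <- caninehd_single_breed_cnvrs()
  expect_equal(nrow(tab), 15)
  expect_equal(length(unique(tab$breed)), 12)
  # frequencies in the published 17-42% range
  expect_true(all(tab$freq >= 0.17 & tab$freq <= 0.42))
  # the dosage table lists 23 gene entries in 9 CNVRs
  dg <- caninehd_dosage_genes()
  expect_equal(nrow(dg), 23)
  expect_equal(length(unique(dg$cnvr_id)), 9)
})
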