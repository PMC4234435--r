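tiny_manifest <- function(pos, chrom = "1") {
  data.frame(snp_id = sprintf("t%03d", seq_along(pos)), chrom = chrom,
             pos = pos, gc = 0.5, stringsAsFactors = FALSE)
}

test_that("Viterbi equals the exhaustive-path maximum on small instances", {
  set.seed(101)
  for (case in 1:4) {
    n <- sample(4:8, 1)
    pos <- cumsum(sample(c(5000, 50000, 500000), n, replace = TRUE))
    mf <- tiny_manifest(pos)
    pfb <- runif(n, 0.05, 0.95)
    lrr <- rnorm(n, sample(c(-0.66, 0, 0.4), 1), 0.3)
    baf <- runif(n)
    params <- hmm_params(sample(c("Q", "P"), 1))
    sg <- sample_signal("x", lrr, baf)
    E <- hmm_emissions(lrr, baf, pfb, params)
    path <- viterbi_segment(sg, mf, params, pfb)
    expect_equal(path_score(path, E, pos, params),
                 brute_force_best_path_score(E, pos, params),
                 tolerance = 1e-9)
  }
})

test_that("a clean diploid signal segments as all-diploid", {
  n <- 200
  mf <- tiny_manifest(seq_len(n) * 10000)
  pfb <- rep(0.5, n)
  set.seed(2)
  baf <- sample(c(0, 0.5, 1), n, replace = TRUE)
  sg <- sample_signal("x", rep(0, n), baf)
  path <- viterbi_segment(sg, mf, hmm_params("Q"), pfb)
  expect_true(all(path == 2L))
})

test_that("a planted het deletion is segmented with at most 1-SNP slack", {
  set.seed(14)
  n <- 200
  mf <- tiny_manifest(seq_len(n) * 13000)
  pfb <- runif(n, 0.05, 0.95)
  state <- rep(2L, n); state[90:109] <- 1L
  lrr <- rnorm(n, lrr_state_means()[as.character(state)], 0.15)
  k <- rbinom(n, state, pfb)
  baf <- pmin(1, pmax(0, k / state + rnorm(n, 0, 0.03)))
  sg <- sample_signal("x", lrr, baf)
  path <- viterbi_segment(sg, mf, hmm_params("Q"), pfb)
  expect_true(all(path[92:107] == 1L))          # core of the segment
  expect_true(all(path[seq_len(88)] == 2L))     # flanks stay diploid
  expect_true(all(path[111:n] == 2L))
})

test_that("call extraction yields scored maximal runs", {
  n <- 30
  mf <- tiny_manifest(seq_len(n) * 10000)
  pfb <- rep(0.5, n)
  sg <- sample_signal("x", rep(0, n), rep(0.5, n))
  params <- hmm_params("Q")

  expect_equal(nrow(extract_calls(rep(2L, n), sg, mf, params, pfb)), 0)

  path <- rep(2L, n); path[10] <- 3L
  calls <- extract_calls(path, sg, mf, params, pfb)
  expect_equal(calls$n_snps, 1L)  # kept here; SNP-span filtering is separate

  # LBF additivity: a run's score equals the sum over its SNPs of the
  # independently computed emission log ratio
  path2 <- rep(2L, n); path2[5:12] <- 1L
  calls2 <- extract_calls(path2, sg, mf, params, pfb)
  manual <- sum(vapply(5:12, function(i) {
    e <- hmm_emissions(sg$lrr[i], sg$baf[i], pfb[i], params)
    e[1, 2] - e[1, 3]
  }, 0))
  expect_equal(calls2$lbf, manual, tolerance = 1e-10)
  # and equals the sum of the two half-runs
  half <- function(i1, i2) {
    p <- rep(2L, n); p[i1:i2] <- 1L
    extract_calls(p, sg, mf, params, pfb)$lbf
  }
  expect_equal(calls2$lbf, half(5, 8) + half(9, 12), tolerance = 1e-10)
})

test_that("call filters implement the span, region and LBF rules", {
  calls <- data.frame(
    sample = "a", chrom = c("1", "1", "2", "2", "2"),
    start = c(1e6, 14e6, 1e6, 2e6, 3e6),
    end = c(1.1e6, 14.2e6, 1.1e6, 2.1e6, 3.1e6),
    copy_state = 1L, n_snps = c(4L, 10L, 10L, 10L, 10L),
    lbf = c(50, 50, 9.9, 10, 30), profile = "Q", stringsAsFactors = FALSE)
  excl <- caninehd_exclusion_regions()

  out <- filter_calls(calls, min_snps = 5, exclusion_regions = excl,
                      lbf_threshold = 10)
  # 4-SNP call dropped; call inside chr1:13-15.7 Mb dropped; LBF 9.9 dropped
  expect_equal(nrow(out), 2)
  expect_setequal(out$lbf, c(10, 30))

  # P-profile convention: no LBF filter
  outp <- filter_calls(calls, min_snps = 5, exclusion_regions = excl,
                       lbf_threshold = NULL)
  expect_equal(nrow(outp), 3)
})

test_that("raising the LBF threshold filters monotonically", {
  calls <- small_calls()$raw_q
  prev <- Inf
  for (thr in c(0, 10, 20, 30, 50)) {
    n <- nrow(filter_calls(calls, 5, NULL, thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the stringent Q list is always a subset of the relaxed list", {
  calls <- small_calls()
  key <- function(df) paste(df$sample, df$chrom, df$start, df$end)
  expect_true(all(key(calls$stringent_q) %in% key(calls$relaxed_q)))
  # call intervals within one sample and profile never overlap
  for (s in unique(calls$relaxed_q$sample)) {
    cs <- calls$relaxed_q[calls$relaxed_q$sample == s, ]
    gr <- GenomicRanges::GRanges(cs$chrom, IRanges::IRanges(cs$start, cs$end))
    expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))
  }
})

test_that("an empty cohort produces three empty call tables", {
  out <- call_cohort(list(), data.frame(), run_config())
  expect_equal(nrow(out$relaxed_q), 0)
  expect_equal(nrow(out$stringent_q), 0)
  expect_equal(nrow(out$p), 0)
})

test_that("planted variants are hit by relaxed Q calls in their carriers", {
  co <- small_cohort()
  calls <- small_calls()
  hit <- 0L
  for (r in seq_len(nrow(co$truths))) {
    tr <- co$truths[r, ]
    if (tr$n_snps < 8) next
    carriers <- truth_carriers(tr)
    cs <- calls$relaxed_q
    ok <- any(cs$sample %in% carriers & cs$chrom == tr$chrom &
                cs$start <= tr$end & cs$end >= tr$start)
    hit <- hit + ok
  }
  n_eval <- sum(co$truths$n_snps >= 8)
  expect_gte(hit / n_eval, 0.9)
})
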