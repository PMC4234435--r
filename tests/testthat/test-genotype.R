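toy_cnvrs <- function() {
  data.frame(id = 1:2, chrom = c("1", "1"),
             start = c(100000, 400000), end = c(200000, 500000),
             stringsAsFactors = FALSE)
}

toy_call <- function(sample, start, end, state = 1L, chrom = "1") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             copy_state = state, n_snps = 10L, lbf = 20, profile = "Q",
             stringsAsFactors = FALSE)
}

test_that("samples without calls genotype as diploid everywhere", {
  gt <- genotype_samples(toy_cnvrs(), empty_calls(), c("a", "b"))
  expect_true(all(gt$matrix == 2L))
  expect_equal(dim(gt$matrix), c(2L, 2L))
})

test_that("a contained relaxed call sets the cell to its copy state", {
  gt <- genotype_samples(toy_cnvrs(), toy_call("a", 110000, 190000, 1L),
                         c("a", "b"))
  expect_equal(gt$matrix["1", "a"], 1L)
  expect_equal(gt$matrix["1", "b"], 2L)
  expect_equal(gt$matrix["2", "a"], 2L)
  # the supporting call is auditable and overlaps the CNVR
  expect_equal(gt$support$cnvr_id, 1)
  expect_gte(gt$support$overlap_bp, 1)
})

test_that("a call spanning two CNVRs goes to the larger overlap only", {
  # overlaps CNVR1 by 30 kb and CNVR2 by 3 kb
  call <- toy_call("a", 170001, 403000, 3L)
  ov1 <- overlap_bp(list(chrom = "1", start = 170001, end = 403000),
                    list(chrom = "1", start = 100000, end = 200000))
  ov2 <- overlap_bp(list(chrom = "1", start = 170001, end = 403000),
                    list(chrom = "1", start = 400000, end = 500000))
  expect_equal(c(ov1, ov2), c(30000, 3001))  # brute-force check of the setup
  gt <- genotype_samples(toy_cnvrs(), call, "a")
  expect_equal(gt$matrix["1", "a"], 3L)
  expect_equal(gt$matrix["2", "a"], 2L)
})

test_that("conflicting same-sample states resolve to the larger overlap", {
  calls <- rbind(toy_call("a", 100000, 180000, 1L),   # 80,001 bp overlap
                 toy_call("a", 185000, 200000, 3L))   # 15,001 bp overlap
  gt <- genotype_samples(toy_cnvrs()[1, ], calls, "a")
  expect_equal(gt$matrix["1", "a"], 1L)
})

test_that("calls from unknown samples are rejected", {
  expect_error(genotype_samples(toy_cnvrs(), toy_call("zz", 1e5, 2e5), "a"),
               "zz")
})

test_that("singleton removal conserves counts and flags zero carriers", {
  m <- matrix(2L, 5, 4, dimnames = list(as.character(1:5),
                                        paste0("s", 1:4)))
  m[1, 1] <- 1L            # singleton
  m[2, c(1, 2)] <- 3L      # kept
  m[3, 1:3] <- 1L          # kept
  m[4, 2] <- 4L            # singleton
  # row 5: zero carriers, kept but flagged
  out <- suppressMessages(remove_singletons(m))
  expect_setequal(out$singletons, c("1", "4"))
  expect_equal(out$zero_carrier, "5")
  expect_equal(nrow(out$matrix) + length(out$singletons), nrow(m))
  expect_true(all(c("2", "3", "5") %in% rownames(out$matrix)))
})

test_that("CNVR types follow the genotype composition", {
  m <- matrix(2L, 3, 3, dimnames = list(as.character(1:3), paste0("s", 1:3)))
  m[1, ] <- c(1L, 1L, 0L)
  m[2, 1:2] <- c(1L, 3L)
  m[3, 1:2] <- c(3L, 4L)
  cls <- classify_cnvr_types(m)
  expect_equal(cls$type, c("del", "del/dupl", "dupl"))
  expect_equal(cls$carriers, c(3L, 2L, 2L))
})

test_that("size summaries bin and stratify lengths correctly", {
  s <- data.frame(length = c(10000, 60000, 120000), type = "del")
  sz <- summarize_sizes(s)
  expect_equal(sz$histogram$bin_start, c(0, 50000, 100000))
  expect_equal(sz$histogram$count, c(1L, 1L, 1L))
  expect_equal(unname(sz$strata), c(2L, 1L, 0L))
  # stratum boundaries: 100 kb goes to the middle, 1 Mb stays in the middle
  sz2 <- summarize_sizes(data.frame(length = c(99999, 100000, 1e6, 1e6 + 1),
                                    type = "del"))
  expect_equal(unname(sz2$strata), c(1L, 2L, 1L))
  expect_equal(summarize_sizes(data.frame(length = 7, type = "del"))$median_all, 7)
  expect_equal(sum(sz2$strata), 4L)
})

test_that("deletion/duplication length comparison is a Welch t-test", {
  same <- data.frame(length = rep(c(1e5, 2e5, 3e5), 2),
                     type = rep(c("del", "dupl"), each = 3))
  res <- compare_del_dup_lengths(same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  set.seed(8)
  strong <- data.frame(length = c(rnorm(30, 1e5, 1e4), rnorm(30, 2e5, 1e4)),
                       type = rep(c("del", "dupl"), each = 30))
  expect_lt(compare_del_dup_lengths(strong)$p_value, 1e-10)

  expect_error(compare_del_dup_lengths(
    data.frame(length = c(1, 2, 3), type = c("del", "dupl", "dupl"))),
    "at least 2")
})

test_that("the t-test p-value agrees with a permutation-null oracle", {
  set.seed(99)
  del <- rnorm(12, 150000, 40000)
  dup <- rnorm(15, 200000, 40000)
  s <- data.frame(length = c(del, dup),
                  type = rep(c("del", "dupl"), c(12, 15)))
  p_t <- compare_del_dup_lengths(s)$p_value
  # 100,000-permutation two-sided mean-difference test
  x <- c(del, dup)
  obs <- abs(mean(del) - mean(dup))
  n1 <- length(del)
  perm <- replicate(1e5, {
    i <- sample.int(length(x), n1)
    abs(mean(x[i]) - mean(x[-i]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_t - p_perm), 0.01)
})
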