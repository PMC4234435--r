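test_that("manifest SNP density matches the configured spacing", {
  cfg <- sim_config(n_chroms = 1, seed = 11)
  mf <- generate_manifest(cfg)
  expected <- 40e6 / 13000  # ~3077
  expect_gt(nrow(mf), expected * 0.9)
  expect_lt(nrow(mf), expected * 1.1)
  expect_true(all(mf$gc >= 0.2 & mf$gc <= 0.8))
  # identical on re-run with the same seed
  expect_identical(generate_manifest(cfg), mf)
  expect_error(generate_manifest(
    sim_config(n_chroms = 1, chrom_length_bp = 40e6,
               mean_snp_spacing_bp = 5e7, seed = 1)),
    "spacing")
})

test_that("truth planting honours category plans and carrier arithmetic", {
  cfg1 <- sim_config(n_chroms = 1, n_shared = 0, n_single_breed = 0,
                     n_singleton = 1, seed = 5)
  mf <- generate_manifest(cfg1)
  tr <- plant_truth_cnvs(cfg1, mf)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$category, "singleton")
  expect_length(truth_carriers(tr[1, ]), 1)

  # frequency 0.33 in a 12-sample breed -> 4 carriers
  cfg2 <- sim_config(n_chroms = 1, n_shared = 0, n_single_breed = 3,
                     n_singleton = 0, single_breed_freq = c(0.33, 0.33),
                     seed = 6)
  tr2 <- plant_truth_cnvs(cfg2, generate_manifest(cfg2))
  expect_true(all(vapply(seq_len(3), function(r)
    length(truth_carriers(tr2[r, ])), 0L) == 4L))
  # single-breed carriers all come from one breed
  samples <- attr(tr2, "samples")
  for (r in seq_len(3)) {
    br <- unique(samples$breed[samples$sample %in% truth_carriers(tr2[r, ])])
    expect_length(br, 1)
  }
})

test_that("planted spans match an independent SNP count inside the interval", {
  co <- small_cohort()
  for (r in seq_len(nrow(co$truths))) {
    n_inside <- sum(co$manifest$chrom == co$truths$chrom[r] &
                      co$manifest$pos >= co$truths$start[r] &
                      co$manifest$pos <= co$truths$end[r])
    expect_equal(n_inside, co$truths$n_snps[r])
    expect_gte(n_inside, 5)
  }
  # planted variants are mutually non-overlapping
  gr <- GenomicRanges::GRanges(co$truths$chrom,
                               IRanges::IRanges(co$truths$start,
                                                co$truths$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) != 1), 0)
})

test_that("simulated LRR matches the five-state emission model", {
  # no CNVs, no wave: per-sample mean LRR concentrates at 0
  cfg <- sim_config(n_chroms = 1, n_shared = 0, n_single_breed = 0,
                    n_singleton = 0, breeds = c(A = 3L),
                    bad_sample_frac = 0, seed = 9)
  co <- simulate_cohort(cfg)
  expect_gt(nrow(co$manifest), 3000)
  for (sg in co$signals) expect_lt(abs(mean(sg$lrr)), 0.01)

  # planted het deletion: region mean near -0.66, BAF avoids 0.5
  cfg2 <- sim_config(n_chroms = 1, n_shared = 1, n_single_breed = 0,
                     n_singleton = 0, breeds = c(A = 6L, B = 6L),
                     states = 1L, span_snps = c(60L, 80L),
                     shared_freq = c(0.5, 0.5), bad_sample_frac = 0, seed = 10)
  co2 <- simulate_cohort(cfg2)
  tr <- co2$truths[1, ]
  inside <- co2$manifest$pos >= tr$start & co2$manifest$pos <= tr$end
  expect_gte(sum(inside), 50)
  for (s in truth_carriers(tr)) {
    sg <- co2$signals[[s]]
    expect_lt(abs(mean(sg$lrr[inside]) + 0.66), 0.05)
    expect_lt(mean(sg$baf[inside] > 0.4 & sg$baf[inside] < 0.6), 0.02)
  }
})

test_that("the noise-free limit reproduces the state means exactly", {
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 5e6,
                    n_shared = 1, n_single_breed = 0, n_singleton = 0,
                    breeds = c(A = 2L, B = 2L), states = 3L,
                    shared_freq = c(1, 1), lrr_sd = 1e-6, baf_sd = 1e-6,
                    bad_sample_frac = 0, seed = 12)
  co <- simulate_cohort(cfg)
  tr <- co$truths[1, ]
  inside <- co$manifest$pos >= tr$start & co$manifest$pos <= tr$end
  carrier <- truth_carriers(tr)[1]
  expect_equal(round(co$signals[[carrier]]$lrr[inside], 4),
               rep(0.40, sum(inside)))
  expect_equal(round(co$signals[[carrier]]$lrr[!inside], 4),
               rep(0, sum(!inside)))
})

test_that("truth states are reflected in the signal (closest state mean)", {
  co <- small_cohort()
  mu <- lrr_state_means()
  for (r in seq_len(nrow(co$truths))) {
    tr <- co$truths[r, ]
    if (tr$n_snps < 20) next
    inside <- co$manifest$chrom == tr$chrom &
      co$manifest$pos >= tr$start & co$manifest$pos <= tr$end
    for (s in truth_carriers(tr)) {
      m <- mean(co$signals[[s]]$lrr[inside])
      expect_equal(names(which.min(abs(mu - m))), as.character(tr$copy_state))
    }
  }
})

test_that("same seed reproduces the identical cohort", {
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 8e6,
                    breeds = c(A = 4L), n_shared = 1, n_single_breed = 1,
                    n_singleton = 0, seed = 33)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truths, c2$truths)
  expect_identical(lapply(c1$signals, `[[`, "lrr"),
                   lapply(c2$signals, `[[`, "lrr"))
})

test_that("bad samples exceed the QC noise threshold", {
  cfg <- sim_config(n_chroms = 1, n_shared = 0, n_single_breed = 0,
                    n_singleton = 0, breeds = c(A = 10L),
                    bad_sample_frac = 0.3, seed = 21)
  co <- simulate_cohort(cfg)
  expect_length(co$bad_samples, 3)
  for (s in co$bad_samples) expect_gt(sd(co$signals[[s]]$lrr), 0.25)
  for (s in setdiff(names(co$signals), co$bad_samples)) {
    expect_lt(sd(co$signals[[s]]$lrr), 0.25)
  }
})
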