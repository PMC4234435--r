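# Shared fixtures, built in code. The small cohort is computed lazily once
# per test run and reused by several files.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- sim_config(n_chroms = 2, chrom_length_bp = 12e6,
                      breeds = c(A = 6L, B = 6L),
                      n_shared = 2, n_single_breed = 2, n_singleton = 1,
                      bad_sample_frac = 0, seed = 2024)
    .fixture_env$cohort <- simulate_cohort(cfg)
  }
  .fixture_env$cohort
}

small_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    co <- small_cohort()
    .fixture_env$calls <- suppressMessages(
      call_cohort(co$signals, co$manifest, run_config(),
                  pfb = co$pfb))
  }
  .fixture_env$calls
}

# a deterministic random call table on one chromosome, for interval-merging
# property tests
random_call_table <- function(n, seed) {
  set.seed(seed)
  start <- sample(1:500000, n)
  width <- sample(1000:80000, n, replace = TRUE)
  data.frame(sample = sample(sprintf("s%02d", 1:8), n, replace = TRUE),
             chrom = "1", start = start, end = start + width,
             copy_state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
             n_snps = sample(5:30, n, replace = TRUE),
             lbf = stats::runif(n, 5, 60), profile = "Q",
             stringsAsFactors = FALSE)
}

# independent brute-force maximum over all 5^n state paths; shares only the
# emission/transition definitions with the implementation, not the dynamic
# program
brute_force_best_path_score <- function(E, pos, params) {
  n <- nrow(E)
  grid <- as.matrix(expand.grid(rep(list(1:5), n)))
  score <- log(params$pi)[grid[, 1]] + E[cbind(1, grid[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      A <- log(hmm_transition(pos[t] - pos[t - 1], params))
      score <- score + A[cbind(grid[, t - 1], grid[, t])] +
        E[cbind(t, grid[, t])]
    }
  }
  max(score)
}

# score of a given path under the same model components
path_score <- function(path, E, pos, params) {
  s <- path + 1L
  n <- length(s)
  sc <- log(params$pi)[s[1]] + E[1, s[1]]
  if (n > 1) {
    for (t in 2:n) {
      A <- log(hmm_transition(pos[t] - pos[t - 1], params))
      sc <- sc + A[s[t - 1], s[t]] + E[t, s[t]]
    }
  }
  sc
}
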