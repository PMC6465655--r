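# Shared fixtures are built once per test run and memoised here; everything
# is generated in code (no stored data files).
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# A 40x scaled-down genome with all 24 chromosomes: fast to simulate but
# structurally identical to the paper-scale panel.
test_chrom_sizes <- function() round(default_chrom_sizes() / 40)

test_panel <- function() memo("test_panel", function() {
  generate_panel_layout(test_chrom_sizes(), n_backbone = 800,
                        backbone_length = 100,
                        hotspot_spec = NULL,
                        fixed_counts = c(X = 44, Y = 10))
})

# 20-sample euploid background on the small panel, 6e5 reads/sample.
test_cohort <- function() memo("test_cohort", function() {
  simulate_reference_cohort(test_panel(), n_samples = 20, total_reads = 6e5,
                            seed = 11)
})

test_baseline <- function() memo("test_baseline", function() {
  build_baseline(test_cohort(), test_panel())
})

# Paper-scale background at 2M reads (aneuploidy-arm conditions).
paper_fixture <- function() memo("paper_fixture", function() {
  panel <- paper_panel()
  cohort <- simulate_reference_cohort(panel, n_samples = 68,
                                      total_reads = 2e6, seed = 11)
  list(panel = panel, cohort = cohort,
       baseline = build_baseline(cohort, panel, segment_background = FALSE))
})

# Exhaustive dynamic-programming oracle: the minimum total squared error of
# any piecewise-constant fit with exactly k segments (O(k n^2), fine for
# n <= a few hundred). Independent of the wavelet segmentation under test.
dp_best_sse <- function(z, k) {
  n <- length(z)
  cs <- c(0, cumsum(z)); cs2 <- c(0, cumsum(z^2))
  sse <- function(a, b) {          # segment z[a..b]
    s <- cs[b + 1] - cs[a]
    (cs2[b + 1] - cs2[a]) - s^2 / (b - a + 1)
  }
  cost <- matrix(Inf, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n)
    cost[m, j] <- min(vapply((m - 1):(j - 1),
                             function(t) cost[m - 1, t] + sse(t + 1, j),
                             numeric(1)))
  cost[k, n]
}

segmentation_sse <- function(z, segs) {
  sum((z - nipt3:::haarseg_reconstruct(z, segs))^2)
}

# A step profile: baseline 0 with z[lo..hi] shifted by `height`, plus
# N(0, sigma) noise.
step_profile <- function(n, lo, hi, height, sigma = 0, seed = 1) {
  mu <- rep(0, n); mu[lo:hi] <- height
  if (sigma > 0) mu <- mu + with_seed(seed, stats::rnorm(n, 0, sigma))
  mu
}

with_seed <- nipt3:::with_seed
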