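test_that("1M-read standardization is exact proportional scaling", {
  expect_equal(normalize_counts(c(2, 3, 5)), c(2e5, 3e5, 5e5))
  expect_equal(normalize_counts(rep(7, 40)), rep(1e6 / 40, 40))
  expect_error(normalize_counts(c(0, 0, 0)), "zero total")
  # scoped normalization sums to 1e6 over the scope only
  x <- c(10, 20, 30, 40)
  expect_equal(sum(normalize_counts(x, scope = c(1, 3))), 1e6)
  p <- test_panel()
  s <- test_cohort()[[1]]
  expect_equal(sum(normalize_counts(s, p, "autosomal")), 1e6)
  expect_equal(sum(normalize_counts(s, p, "whole")), 1e6)
})

test_that("baseline statistics behave under degenerate and scaled input", {
  p <- test_panel()
  s <- test_cohort()[[1]]
  # a cohort of identical samples has zero variance everywhere; the baseline
  # records that honestly and scoring against it is refused
  twin <- lapply(1:3, function(i) { x <- s; x$sample_id <- paste0("s", i); x })
  b0 <- build_baseline(twin, p, segment_background = FALSE)
  expect_true(all(b0$region_sd == 0))
  expect_true(all(b0$chrom_auto$sd == 0))
  expect_error(chromosome_z(s, b0), "degenerate")
  expect_error(region_z(s, b0), "degenerate")

  # an isolated zero-variance region is floored to the smallest positive SD
  cohort_f <- test_cohort()
  flat <- which(p$kind == "backbone" & p$chrom == "1")[1]
  # a region with zero counts in every sample has zero normalized variance
  for (i in seq_along(cohort_f)) cohort_f[[i]]$counts[flat] <- 0
  bf <- build_baseline(cohort_f, p, segment_background = FALSE)
  expect_true(all(bf$region_sd > 0))
  expect_equal(bf$region_sd[flat], min(bf$region_sd[-flat]))

  # library size is removed: scaling one sample's counts changes nothing
  cohort <- test_cohort()
  scaled <- cohort
  scaled[[3]]$counts <- scaled[[3]]$counts * 4
  b1 <- build_baseline(cohort, p, segment_background = FALSE)
  b2 <- build_baseline(scaled, p, segment_background = FALSE)
  expect_equal(b1$region_mean, b2$region_mean)
  expect_equal(b1$chrom_auto, b2$chrom_auto)

  expect_error(build_baseline(cohort[1], p), "at least 2")
  bad <- cohort; bad[[1]]$counts <- bad[[1]]$counts[-1]
  expect_error(build_baseline(bad, p), "dimension")
})

test_that("chromosome means match the uniform-weight expectation", {
  # under uniform capture weights, each autosome's chromosome statistic is
  # (1e6 / n_autosomal_regions) in expectation
  b <- test_baseline()
  p <- test_panel()
  bb <- p[p$kind == "backbone", ]
  n_auto <- sum(bb$chrom %in% as.character(1:22))
  expect_equal(b$chrom_auto$mean, rep(1e6 / n_auto, 22), tolerance = 0.01)
})

test_that("background samples score as euploid against a leave-one-out baseline", {
  p <- test_panel()
  cohort <- test_cohort()
  pairs <- 0; ok <- 0
  for (i in 1:10) {
    b <- build_baseline(cohort[-i], p, segment_background = FALSE)
    cz <- chromosome_z(cohort[[i]], b)
    z <- cz$z[cz$chrom %in% as.character(1:22)]
    pairs <- pairs + length(z)
    ok <- ok + sum(abs(z) < 3)
  }
  expect_gte(ok / pairs, 0.95)
})

test_that("baseline bundles round-trip through JSON and guard the panel", {
  p <- test_panel()
  b <- build_baseline(test_cohort(), p)
  path <- tempfile(fileext = ".json")
  save_baseline(b, path)
  b2 <- load_baseline(path)
  s <- test_cohort()[[2]]
  expect_equal(chromosome_z(s, b2), chromosome_z(s, b))
  expect_equal(b2$median_interval_segment, b$median_interval_segment)

  other <- generate_panel_layout(c(`1` = 1e6, `2` = 1e6), 10, 50)
  expect_error(call_cnvs(segment_sample(region_z(s, b)), b, panel = other),
               "checksum")
})
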