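test_that("simulated counts honour totals, determinism and the dose model", {
  p <- test_panel()
  tr <- sample_truth(0.2, sex_karyotype = "XX", sample_id = "eu")
  for (reads in c(1e4, 3e5)) {
    s <- simulate_region_counts(p, tr, total_reads = reads, seed = 5)
    expect_equal(sum(s$counts), reads)
    expect_true(all(s$counts >= 0))
  }
  s1 <- simulate_region_counts(p, tr, seed = 5)
  s2 <- simulate_region_counts(p, tr, seed = 5)
  s3 <- simulate_region_counts(p, tr, seed = 6)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))

  # XX fetus: no Y dose at all
  bb <- p[p$kind == "backbone", ]
  expect_true(all(s1$counts[bb$chrom == "Y"] == 0))

  # XY fetus: Y regions carry f/2 of an autosomal dose
  trm <- sample_truth(0.2, sex_karyotype = "XY", sample_id = "m")
  sm <- simulate_region_counts(p, trm, total_reads = 2e6, seed = 5,
                               dispersion = 0)
  ratio <- mean(sm$counts[bb$chrom == "Y"]) / mean(sm$counts[bb$chrom == "1"])
  expect_equal(ratio, 0.1, tolerance = 0.05)
})

test_that("fetal copy gains shift expected dose by 1 + f/2", {
  # Monte-Carlo check of the dose model against its closed form
  p <- test_panel()
  bb <- p[p$kind == "backbone", ]
  tr <- sample_truth(0.2, cnvs = data.frame(chrom = "2", start = 0, end = 3e6,
                                            copy_delta = 1),
                     sample_id = "dup")
  dup <- bb$chrom == "2" & bb$start < 3e6
  dip <- bb$chrom == "1"
  seeds <- nipt3:::child_seeds(11, 200)
  rat <- vapply(seeds, function(sd) {
    s <- simulate_region_counts(p, tr, total_reads = 3e5, dispersion = 0,
                                seed = sd)
    mean(s$counts[dup]) / mean(s$counts[dip])
  }, numeric(1))
  expect_equal(mean(rat), 1.10, tolerance = 0.01)

  # a loss shifts by 1 - f/2
  trl <- sample_truth(0.2, cnvs = data.frame(chrom = "2", start = 0, end = 3e6,
                                             copy_delta = -1),
                      sample_id = "del")
  ratl <- vapply(seeds[1:100], function(sd) {
    s <- simulate_region_counts(p, trl, total_reads = 3e5, dispersion = 0,
                                seed = sd)
    mean(s$counts[dup]) / mean(s$counts[dip])
  }, numeric(1))
  expect_equal(mean(ratl), 0.90, tolerance = 0.01)
})

test_that("overdispersion only ever widens the count distribution", {
  p <- test_panel()
  tr <- sample_truth(0.2, sample_id = "eu")
  var_at <- function(disp) {
    counts <- vapply(nipt3:::child_seeds(3, 1000), function(sd)
      simulate_region_counts(p, tr, total_reads = 2e5, dispersion = disp,
                             seed = sd)$counts[1], numeric(1))
    stats::var(counts)
  }
  v0 <- var_at(0)
  expect_lt(v0, var_at(0.002))
  expect_lt(v0, var_at(0.01))
})

test_that("reference cohorts are reproducible and need >= 2 samples", {
  p <- test_panel()
  c1 <- simulate_reference_cohort(p, n_samples = 4, total_reads = 1e5, seed = 9)
  c2 <- simulate_reference_cohort(p, n_samples = 4, total_reads = 1e5, seed = 9)
  c3 <- simulate_reference_cohort(p, n_samples = 4, total_reads = 1e5, seed = 10)
  expect_length(c1, 4)
  expect_identical(sapply(c1, `[[`, "counts"), sapply(c2, `[[`, "counts"))
  expect_false(identical(sapply(c1, `[[`, "counts"),
                         sapply(c3, `[[`, "counts")))
  expect_error(simulate_reference_cohort(p, n_samples = 1), "at least 2")
})

test_that("pileup simulation follows the mixture fraction model", {
  mk <- function(m, f) sample_truth(0.2, maternal_genotypes = c(L1 = m),
                                    fetal_genotypes = c(L1 = f),
                                    sample_id = "x")
  # mother AB, fetus AB: balanced alleles regardless of fetal fraction
  pile <- simulate_pileups(mk("AB", "AB"), mean_depth = 20000,
                           error_rate = 0, seed = 3)
  expect_equal(pile$alt_count / (pile$ref_count + pile$alt_count), 0.5,
               tolerance = 0.02)
  # mother AA, fetus AB: alt fraction f/2
  pile <- simulate_pileups(mk("AA", "AB"), mean_depth = 20000,
                           error_rate = 0, seed = 3)
  expect_equal(pile$alt_count / (pile$ref_count + pile$alt_count), 0.10,
               tolerance = 0.02)
  # Mendelian violation is refused at truth construction
  expect_error(mk("AA", "BB"), "non-Mendelian")
  # deterministic
  t2 <- mk("AB", "AA")
  expect_identical(simulate_pileups(t2, seed = 4), simulate_pileups(t2, seed = 4))
})

test_that("count matrices round-trip through TSV", {
  p <- test_panel()
  cohort <- simulate_reference_cohort(p, n_samples = 3, total_reads = 1e5,
                                      seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_counts_tsv(cohort, p, path)
  back <- read_counts_tsv(path)
  expect_equal(sapply(back, `[[`, "counts"), sapply(cohort, `[[`, "counts"))
  expect_equal(sapply(back, `[[`, "sample_id"),
               sapply(cohort, `[[`, "sample_id"))
})
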