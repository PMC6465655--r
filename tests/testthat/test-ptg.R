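test_that("the admissible pseudo-tetraploid space is derived by enumeration", {
  space <- pseudo_tetraploid_space()
  expect_length(space, 7)                       # 9 pairs minus 2 violations
  expect_setequal(space, c("AAAA", "AAAB", "ABAA", "ABAB", "ABBB",
                           "BBAB", "BBBB"))
  expect_false("AABB" %in% space)               # mother AA, fetus BB
  expect_false("BBAA" %in% space)

  inf <- informative_combinations()
  expect_length(inf, 4)
  expect_setequal(inf, c("AAAB", "ABAA", "ABBB", "BBAB"))
  expect_true(all(inf %in% space))
  expect_false("ABAB" %in% inf)
})

test_that("expected mixture fractions follow the two-genome dosage model", {
  expect_equal(expected_alt_fraction("AAAB", 0.2), 0.10)
  expect_equal(expected_alt_fraction("ABAB", 0.07), 0.50)
  expect_equal(expected_alt_fraction("ABAB", 0.41), 0.50)
  expect_equal(expected_alt_fraction("BBAB", 0.2), 0.90)
  expect_equal(expected_alt_fraction("ABAA", 0.2), 0.40)
  # limits: f -> 0 recovers maternal-only fractions, f -> 1 fetal-only
  f0 <- expected_alt_fraction(pseudo_tetraploid_space(), 1e-9)
  expect_equal(f0, c(0, 0, 0.5, 0.5, 0.5, 1, 1), tolerance = 1e-6)
  f1 <- expected_alt_fraction(pseudo_tetraploid_space(), 1 - 1e-9)
  expect_equal(f1, c(0, 0.5, 0, 0.5, 1, 0.5, 1), tolerance = 1e-6)
  expect_error(expected_alt_fraction("AABB", 0.2), "inadmissible")
})

test_that("the binomial locus likelihood matches direct evaluation", {
  # frozen oracle: ln(choose(10,5) * 0.5^10) = -1.4021 (4 d.p.)
  ll <- locus_log_likelihood(list(ref_count = 5, alt_count = 5), "ABAB",
                             f = 0.2, error_rate = 0)
  expect_equal(ll, -1.4021, tolerance = 1e-4)
  # homozygous-reference beats homozygous-alt when no alt reads are seen
  p0 <- list(ref_count = 50, alt_count = 0)
  expect_gt(locus_log_likelihood(p0, "AAAA", 0.2, 0.005),
            locus_log_likelihood(p0, "BBBB", 0.2, 0.005))
  # zero depth is uninformative for every combination
  pz <- list(ref_count = 0, alt_count = 0)
  expect_equal(locus_log_likelihood(pz, pseudo_tetraploid_space(), 0.2),
               rep(0, 7))
  # clamp collision: combos clamped to the same fraction tie exactly
  expect_equal(locus_log_likelihood(p0, "AAAA", 1e-6, 0.005),
               locus_log_likelihood(p0, "AAAB", 1e-6, 0.005))
})

test_that("EM recovers the fetal fraction and is monotone in likelihood", {
  loci <- default_locus_metadata(n_common = 500)[-(1:9), ]
  for (s in 1:3) {
    gt <- simulate_truth_genotypes(loci, seed = s)
    tr <- sample_truth(0.18, maternal_genotypes = gt$maternal,
                       fetal_genotypes = gt$fetal, sample_id = "em")
    pile <- simulate_pileups(tr, mean_depth = 200, seed = s + 100)
    est <- estimate_fetal_fraction_em(pile, prior = hwe_prior(loci$pop_b_freq))
    expect_true(est$converged)
    expect_lt(abs(est$f - 0.18), 0.02)
    expect_true(all(diff(est$loglik) > -1e-6))
    k <- length(est$trajectory)
    expect_lt(abs(est$trajectory[k] - est$trajectory[k - 1]), 0.001)
  }
  # no informative loci: mixture fraction carries no f signal
  flat <- data.frame(locus_id = c("a", "b"), ref_count = c(100, 0),
                     alt_count = c(0, 100))
  expect_warning(est <- estimate_fetal_fraction_em(flat), "no fetal-fraction")
  expect_false(est$converged)
})

test_that("MAP genotyping picks the nearest expected fraction", {
  mk <- function(alt, depth = 200)
    data.frame(locus_id = "L", ref_count = depth - alt, alt_count = alt)
  expect_equal(map_genotypes(mk(101), f = 0.20)$map_combo, "ABAB")
  expect_equal(map_genotypes(mk(0), f = 0.20)$map_combo, "AAAA")
  expect_equal(map_genotypes(mk(21), f = 0.20)$map_combo, "AAAB")
  expect_equal(map_genotypes(mk(21), f = 0.20)$pgc, "AAab")
  # posteriors normalize
  post <- attr(map_genotypes(mk(50), f = 0.20), "posterior")
  expect_equal(rowSums(post), 1, tolerance = 1e-9)
})

test_that("genotype concordance meets the idealized-simulation floor", {
  conc <- ptg_concordance(seed = 11, n_per_combo = 150, f = 0.20, depth = 200)
  expect_gte(conc$overall, 75)
  expect_gte(conc$homozygote_like, 95)
})

test_that("variant detection sensitivity is monotone in f and depth", {
  sens <- function(f, depth, n = 600, seed = 7) {
    m <- rep("AB", n); ft <- rep("AB", n)
    tr <- sample_truth(f, maternal_genotypes = stats::setNames(m, 1:n),
                       fetal_genotypes = stats::setNames(ft, 1:n),
                       sample_id = "s")
    pile <- simulate_pileups(tr, mean_depth = depth, seed = seed)
    calls <- map_genotypes(pile, f = f)
    mean(calls$fetal_call %in% c("AB", "BB"))
  }
  grid <- expand.grid(f = c(0.08, 0.12, 0.16), depth = c(80, 140, 200))
  grid$sens <- mapply(sens, grid$f, grid$depth)
  m <- matrix(grid$sens, 3, 3)        # rows: f, cols: depth
  expect_true(all(apply(m, 2, diff) >= 0))
  expect_true(all(apply(m, 1, diff) >= 0))
})

test_that("disease status aggregates pathogenic alleles per gene", {
  loci <- default_locus_metadata(n_common = 0)
  mk_calls <- function(ids, combos)
    data.frame(locus_id = ids, map_combo = combos,
               pgc = paste0(substr(combos, 1, 2), tolower(substr(combos, 3, 4))),
               fetal_call = substr(combos, 3, 4), posterior = 1,
               stringsAsFactors = FALSE)
  # carrier: one heterozygous pathogenic locus
  calls <- mk_calls(loci$locus_id, rep("AAAA", 9))
  calls$map_combo[3] <- "ABAB"; calls$fetal_call[3] <- "AB"
  vc <- call_variants(calls, loci)
  expect_equal(vc$genes$status[vc$genes$gene == "GJB2"], "carrier")
  expect_equal(vc$loci$reported[3], "heterozygous")
  # compound heterozygote: two GJB2 loci fetal-het -> affected
  calls$map_combo[5] <- "AAAB"; calls$fetal_call[5] <- "AB"
  vc <- call_variants(calls, loci)
  expect_equal(vc$genes$status[vc$genes$gene == "GJB2"], "affected")
  # homozygous alt at one locus -> affected
  calls2 <- mk_calls(loci$locus_id, rep("AAAA", 9))
  calls2$map_combo[7] <- "ABBB"; calls2$fetal_call[7] <- "BB"
  vc2 <- call_variants(calls2, loci)
  expect_equal(vc2$genes$status[vc2$genes$gene == "HBB"], "affected")
  expect_equal(vc2$loci$reported[7], "homozygous")
  # metadata must cover every call
  expect_error(call_variants(mk_calls("nope", "AAAA"), loci), "metadata")
})

test_that("screens serialize to TSV and minimal VCF", {
  loci <- default_locus_metadata(n_common = 50)
  gt <- simulate_truth_genotypes(loci, seed = 4,
                                 force = list("HBB:c.A52T" = c("AB", "AB")))
  tr <- sample_truth(0.21, maternal_genotypes = gt$maternal,
                     fetal_genotypes = gt$fetal, sample_id = "s1")
  pile <- simulate_pileups(tr, mean_depth = 250, seed = 8)
  scr <- screen_single_gene(pile, loci = loci)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_variant_tsv(scr, tsv, sample_id = "s1")
  df <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 9)            # one row per pathogenic locus
  write_variant_vcf(scr, vcf, sample_id = "s1")
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("^#CHROM", lines)))
  # pileup TSV round-trip
  pt <- tempfile(fileext = ".tsv")
  write_pileups_tsv(pile, pt)
  expect_equal(read_pileups_tsv(pt)$alt_count, pile$alt_count)
})
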