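test_that("Z thresholding implements the calling rule exactly", {
  zs <- data.frame(chrom = as.character(1:22), z = 0)
  calls <- call_autosomal_aneuploidy(zs)
  expect_true(all(calls$state == "euploid"))

  zs$z[zs$chrom == "13"] <- 5.53
  calls <- call_autosomal_aneuploidy(zs, z_cut = 3)
  expect_equal(calls$state[calls$chrom == "13"], "trisomy")
  expect_equal(sum(calls$state != "euploid"), 1)

  zs$z[zs$chrom == "13"] <- 0
  zs$z[zs$chrom == "18"] <- 3.68
  expect_equal(call_autosomal_aneuploidy(zs)$state[zs$chrom == "18"], "trisomy")

  zs$z[zs$chrom == "18"] <- -3.2
  expect_equal(call_autosomal_aneuploidy(zs)$state[zs$chrom == "18"], "monosomy")

  expect_error(call_autosomal_aneuploidy(zs[-1, ]), "22 autosomes")
})

test_that("a background sample is self-consistent against its own cohort", {
  b <- test_baseline()
  cz <- chromosome_z(test_cohort()[[5]], b)
  expect_true(all(is.finite(cz$z)))
  expect_true(all(abs(cz$z[cz$chrom %in% as.character(1:22)]) < 4))
})

test_that("trisomy Z grows with fetal fraction and is detected at study scale", {
  fx <- paper_fixture()
  seeds <- nipt3:::child_seeds(11, 3)
  z21 <- vapply(c(0.05, 0.10, 0.20), function(f) {
    tr <- sample_truth(f, aneuploidies = data.frame(chrom = "21",
                                                    state = "trisomy"),
                       sample_id = "t21")
    s <- simulate_region_counts(fx$panel, tr, total_reads = 2e6, seed = seeds[1])
    cz <- chromosome_z(s, fx$baseline)
    cz$z[cz$chrom == "21"]
  }, numeric(1))
  expect_true(all(diff(z21) > 0))
  expect_gt(z21[3], 3)

  # detection power at the study's fetal fractions: 50/50 replicates
  reps <- nipt3:::child_seeds(12, 50)
  hits <- vapply(reps, function(sd) {
    tr <- sample_truth(0.16, aneuploidies = data.frame(chrom = "18",
                                                       state = "trisomy"),
                       sample_id = "t18")
    s <- simulate_region_counts(fx$panel, tr, total_reads = 2e6, seed = sd)
    cz <- chromosome_z(s, fx$baseline)
    cz$z[cz$chrom == "18"] >= 3
  }, logical(1))
  expect_equal(mean(hits), 1)
})

test_that("fetal sex and sex karyotypes are inferred from Y dose and X Z", {
  fx <- paper_fixture()
  run <- function(karyo, f, seed = 21) {
    tr <- sample_truth(f, sex_karyotype = karyo, sample_id = karyo)
    s <- simulate_region_counts(fx$panel, tr, total_reads = 2e6, seed = seed)
    call_aneuploidy(s, fx$baseline)
  }
  xx <- run("XX", 0.20)
  expect_equal(xx$fetal_sex, "XX")
  expect_equal(xx$sex_karyotype, "XX")
  expect_lt(xx$sex_detail$y_median, xx$sex_detail$y_threshold)

  xy <- run("XY", 0.20)
  expect_equal(xy$fetal_sex, "XY")
  expect_equal(xy$sex_karyotype, "XY")
  expect_lte(xy$sex_detail$x_z, -3)   # male X dose vs XX stratum

  x0 <- run("X0", 0.1986)
  expect_equal(x0$sex_karyotype, "X0")
  expect_equal(x0$result, "X0")

  xxy <- run("XXY", 0.1632)
  expect_equal(xxy$sex_karyotype, "XXY")
  expect_gt(xxy$sex_detail$y_median, xxy$sex_detail$y_threshold)
  expect_gt(xxy$sex_detail$x_z, -3)   # X dose at XX level
})

test_that("aneuploidy reports serialize with a summary row", {
  fx <- paper_fixture()
  tr <- sample_truth(0.19, aneuploidies = data.frame(chrom = "21",
                                                     state = "trisomy"),
                     sample_id = "t21")
  s <- simulate_region_counts(fx$panel, tr, total_reads = 2e6, seed = 31)
  call <- call_aneuploidy(s, fx$baseline)
  path <- tempfile(fileext = ".tsv")
  write_aneuploidy_tsv(call, path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 25)          # 24 chromosomes + summary row
  expect_equal(df$state[df$chrom == "result"], call$result)
})
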