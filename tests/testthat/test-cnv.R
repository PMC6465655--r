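test_that("region Z-values implement the standardization exactly", {
  # hand-built 2-chromosome cohort with known per-region mean and SD
  p <- generate_panel_layout(c(`1` = 1e4, `2` = 1e4), n_backbone = 6,
                             backbone_length = 50)
  mk <- function(r1) {
    counts <- c(r1, rep((1e6 - r1) / 5, 5))
    nipt3:::new_region_counts(paste0("s", r1), counts, 1e6)
  }
  cohort <- list(mk(119000), mk(120000), mk(121000))
  b <- build_baseline(cohort, p, segment_background = FALSE)
  expect_equal(b$region_mean[1], 120000)
  expect_equal(b$region_sd[1], 1000)

  zs <- region_z(mk(122000), b)
  expect_equal(zs$z[1], 2)               # mean + 2 SD
  zs0 <- region_z(mk(120000), b)
  expect_equal(zs0$z[1], 0)              # at the mean
})

test_that("the calling criteria are applied conjunctively", {
  stub <- structure(list(median_interval_segment = c(-1, 1),
                         median_interval_sample = c(-0.5, 0.5),
                         panel_checksum = "stub"),
                    class = "nipt_baseline")
  seg <- function(n, span, mean_z, median_z)
    data.frame(chrom = "9", start = 0, end = span, start_index = 1,
               end_index = n, n_regions = n, mean_z = mean_z,
               median_z = median_z)

  called <- call_cnvs(seg(25, 12e6, 2.5, 2.6), stub)
  expect_equal(nrow(called), 1)
  expect_equal(called$direction, "dup")
  expect_equal(called$size, 12e6)

  # each criterion alone vetoes the call
  expect_equal(nrow(call_cnvs(seg(19, 12e6, 3.0, 3.0), stub)), 0)  # regions
  expect_equal(nrow(call_cnvs(seg(25, 8e6, 3.0, 3.0), stub)), 0)   # span
  expect_equal(nrow(call_cnvs(seg(30, 15e6, 0.5, 2.4), stub)), 0)  # mean Z
  expect_equal(nrow(call_cnvs(seg(30, 15e6, 2.5, 1.5), stub)), 0)  # median Z
  # inside the background interval: vetoed even when |median| > 2
  wide <- stub; wide$median_interval_segment <- c(-3, 3)
  expect_equal(nrow(call_cnvs(seg(25, 12e6, 2.5, 2.6), wide)), 0)
  # deletions mirror duplications
  expect_equal(call_cnvs(seg(25, 12e6, -2.5, -2.6), stub)$direction, "del")
})

test_that("simulated duplications raise the affected regions' Z", {
  p <- test_panel()
  b <- test_baseline()
  bb <- p[p$kind == "backbone", ]
  tr <- sample_truth(0.2, cnvs = data.frame(chrom = "4", start = 0, end = 2.5e6,
                                            copy_delta = 1),
                     sample_id = "dup")
  s <- simulate_region_counts(p, tr, total_reads = 6e5, seed = 17)
  zs <- region_z(s, b)
  aff <- zs$chrom == "4" & zs$start < 2.5e6
  expect_gt(mean(zs$z[aff]), 1.5)
  expect_lt(abs(mean(zs$z[zs$chrom == "5"])), 0.5)

  scr <- call_sample_cnvs(s, b, panel = p, min_span = 1e6)
  hit <- scr$calls[scr$calls$chrom == "4", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "dup")
  # boundaries within one inter-region spacing of the simulated truth
  spacing <- median(diff(bb$start[bb$chrom == "4"]))
  idx <- which(bb$chrom == "4" & bb$start < 2.5e6)
  expect_lte(abs(hit$start - bb$start[idx[1]]), spacing)
  expect_lte(abs(hit$end - bb$end[idx[length(idx)]]), spacing)
})

test_that("sex-chromosome segments are suppressed for abnormal karyotypes", {
  p <- test_panel()
  b <- test_baseline()
  tr <- sample_truth(0.2, sex_karyotype = "X0", sample_id = "x0")
  s <- simulate_region_counts(p, tr, total_reads = 6e5, seed = 19)
  scr <- call_sample_cnvs(s, b, panel = p, min_span = 1e6)
  expect_true("X" %in% scr$segments$chrom)
  expect_false(any(scr$calls$chrom %in% c("X", "Y")))
  expect_equal(scr$sex_karyotype, "X0")
  # the same segments are callable when suppression is off
  scr2 <- call_sample_cnvs(s, b, panel = p, min_span = 1e6,
                           suppress_sex = FALSE)
  expect_true(any(scr2$calls$chrom == "X" & scr2$calls$direction == "del"))
})

test_that("CNV calls serialize to TSV and BED", {
  calls <- data.frame(chrom = "9", start = 0, end = 12e6, size = 12e6,
                      n_regions = 30, mean_z = 2.5, median_z = 2.6,
                      direction = "dup", iscn = "x", stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_cnv_tsv(calls, tsv)
  expect_equal(read.table(tsv, header = TRUE, sep = "\t")$size, 12e6)
  write_cnv_bed(calls, bed)
  expect_match(readLines(bed)[1], "^9\t0\t12000000\tdup")
  write_cnv_bed(calls[0, ], bed)
  expect_length(readLines(bed), 0)
})
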