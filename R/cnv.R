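#' Region-level Z-values
#'
#' z_i = (depth_i - region_mean_i) / region_sd_i with autosomal-scope
#' normalization for autosomal regions and whole-panel scope for X/Y
#' (scored against the background stratum matching the sample's inferred
#' fetal sex).
#'
#' @param sample A `region_counts`.
#' @param baseline A `nipt_baseline`.
#' @param sex NULL to infer fetal sex from the chrY median depth, or
#'   "XX"/"XY" to force the sex-chromosome stratum.
#' @return data.frame(chrom, start, end, z) in panel backbone order.
#' @export
region_z <- function(sample, baseline, sex = NULL) {
  check_baseline_sample(sample, baseline)
  n_bb <- nrow(baseline$backbone)
  z <- rep(NA_real_, n_bb)
  if (any(baseline$region_sd == 0))
    stop("background region SD is zero even after flooring; ",
         "the cohort is degenerate")
  d_auto <- normalize_counts(sample$counts, scope = baseline$auto_idx)
  z[baseline$auto_idx] <- (d_auto - baseline$region_mean) / baseline$region_sd

  sexpos <- c(baseline$x_idx, baseline$y_idx)
  if (length(sexpos)) {
    d_whole <- normalize_counts(sample$counts, scope = seq_len(n_bb))
    if (is.null(sex)) {
      y_med <- stats::median(d_whole[baseline$y_idx])
      ref <- baseline$male_y_reference
      sex <- if (!is.na(ref) && y_med >= 0.25 * ref) "XY" else "XX"
    }
    st <- baseline$strata[[sex]] %||% baseline$strata$XX %||% baseline$strata$XY
    z[sexpos] <- (d_whole[sexpos] - st$region_mean) / st$region_sd
  }
  cbind(baseline$backbone, z = z)
}

#' Segment a sample's region Z profile chromosome by chromosome
#'
#' Runs [haarseg_segment()] on each chromosome of a [region_z()] table and
#' annotates the segments with genomic coordinates (span of the covered
#' regions).
#'
#' @param zs A [region_z()] table.
#' @param max_scale,fdr_q HaarSeg parameters.
#' @return data.frame(chrom, start, end, start_index, end_index, n_regions,
#'   mean_z, median_z); indices are per-chromosome region indices.
#' @export
segment_sample <- function(zs, max_scale = 5, fdr_q = 0.001) {
  out <- lapply(unique(zs$chrom), function(cn) {
    zc <- zs[zs$chrom == cn, , drop = FALSE]
    segs <- haarseg_segment(zc$z, max_scale = max_scale, fdr_q = fdr_q)
    segs$chrom <- cn
    segs$start <- zc$start[segs$start_index]
    segs$end <- zc$end[segs$end_index]
    segs
  })
  out <- do.call(rbind, out)
  out[, c("chrom", "start", "end", "start_index", "end_index", "n_regions",
          "mean_z", "median_z")]
}

#' Call CNVs from segments
#'
#' A segment becomes a CNV call iff it meets all four criteria:
#' (1) it covers at least `min_regions` consecutive regions AND spans at
#' least `min_span` bp; (2) its mean Z lies outside `mean_z_range`
#' (\[-0.7, 0.7\]); (3) its median Z lies outside `median_z_range`
#' (\[-2, 2\]); (4) its median Z lies outside the 95% background median
#' interval stored in the baseline. Direction is dup for positive median Z,
#' del for negative.
#'
#' @param segments A [segment_sample()] table.
#' @param baseline A `nipt_baseline` (provides the background interval).
#' @param panel Optional `nipt_panel`; when given, its checksum must match
#'   the baseline's.
#' @param min_regions,min_span,mean_z_range,median_z_range Calling criteria.
#' @param background_interval "segment" (interval over background segment
#'   medians; default) or "sample" (over background per-sample medians).
#' @return data.frame(chrom, start, end, size, n_regions, mean_z, median_z,
#'   direction, iscn).
#' @export
call_cnvs <- function(segments, baseline, panel = NULL,
                      min_regions = 20, min_span = 1e7,
                      mean_z_range = c(-0.7, 0.7), median_z_range = c(-2, 2),
                      background_interval = c("segment", "sample")) {
  background_interval <- match.arg(background_interval)
  if (!is.null(panel) && !identical(panel_checksum(panel), baseline$panel_checksum))
    stop("panel checksum does not match the baseline's panel")
  bg <- if (background_interval == "segment")
    baseline$median_interval_segment %||% baseline$median_interval_sample
  else baseline$median_interval_sample

  keep <- segments$n_regions >= min_regions &
    (segments$end - segments$start) >= min_span &
    (segments$mean_z < mean_z_range[1] | segments$mean_z > mean_z_range[2]) &
    (segments$median_z < median_z_range[1] | segments$median_z > median_z_range[2]) &
    (segments$median_z < bg[1] | segments$median_z > bg[2])
  hits <- segments[keep, , drop = FALSE]
  dir <- ifelse(hits$median_z > 0, "dup", "del")
  out <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                    size = hits$end - hits$start, n_regions = hits$n_regions,
                    mean_z = hits$mean_z, median_z = hits$median_z,
                    direction = dir,
                    iscn = sprintf("seq[GRCh37-sim]%s(%s)(bands unavailable) chr%s:g.%.0f_%.0f%s",
                                   dir, hits$chrom, hits$chrom,
                                   hits$start + 1, hits$end, dir),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full CNV screen of one sample
#'
#' Region Z-values, HaarSeg segmentation per chromosome, and CNV calling.
#' Segments on X/Y are scored but suppressed from the call set when the
#' sample's sex karyotype is abnormal (the event is already reported as an
#' aneuploidy).
#'
#' @inheritParams region_z
#' @inheritParams call_cnvs
#' @param max_scale,fdr_q HaarSeg parameters.
#' @param suppress_sex Suppress X/Y calls for abnormal sex karyotypes
#'   (default TRUE).
#' @return list(segments, calls, sex_karyotype) of class `cnv_screen`.
#' @export
call_sample_cnvs <- function(sample, baseline, panel = NULL,
                             max_scale = 5, fdr_q = 0.001,
                             min_regions = 20, min_span = 1e7,
                             mean_z_range = c(-0.7, 0.7),
                             median_z_range = c(-2, 2),
                             background_interval = c("segment", "sample"),
                             suppress_sex = TRUE) {
  sexinfo <- infer_fetal_sex(sample, baseline)
  zs <- region_z(sample, baseline, sex = sexinfo$fetal_sex)
  segs <- segment_sample(zs, max_scale = max_scale, fdr_q = fdr_q)
  calls <- call_cnvs(segs, baseline, panel = panel, min_regions = min_regions,
                     min_span = min_span, mean_z_range = mean_z_range,
                     median_z_range = median_z_range,
                     background_interval = background_interval)
  if (suppress_sex && sexinfo$sex_karyotype %in% c("X0", "XXY", "other"))
    calls <- calls[!calls$chrom %in% c("X", "Y"), , drop = FALSE]
  structure(list(sample_id = sample$sample_id, segments = segs, calls = calls,
                 sex_karyotype = sexinfo$sex_karyotype),
            class = "cnv_screen")
}

#' @export
print.cnv_screen <- function(x, ...) {
  cat(sprintf("<cnv_screen> %s: %d segments, %d CNV call(s)\n",
              x$sample_id, nrow(x$segments), nrow(x$calls)))
  if (nrow(x$calls))
    print(x$calls[, c("chrom", "start", "end", "size", "median_z", "direction")])
  invisible(x)
}

#' Write CNV calls as TSV / BED
#'
#' @param calls A [call_cnvs()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_tsv <- function(calls, path) write_tsv(calls, path)

#' @rdname write_cnv_tsv
#' @export
write_cnv_bed <- function(calls, path) {
  if (!nrow(calls)) { writeLines(character(0), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(start = calls$start + 1,
                                                end = calls$end),
                               name = paste0(calls$direction, "_",
                                             format(calls$size, scientific = FALSE,
                                                    trim = TRUE), "bp"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
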