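#' Standardize region counts to one million reads
#'
#' depth_i = count_i * 1e6 / sum(counts over scope). The autosomal scope
#' (the 7,631 autosomal backbone regions on the paper-scale panel) is used
#' for autosomal statistics; the whole-panel scope (all 8,171 backbone
#' regions) is used for sex-chromosome statistics.
#'
#' @param counts A `region_counts` object or a numeric count vector in panel
#'   backbone order.
#' @param panel A `nipt_panel`; required when `scope` is "autosomal"/"whole".
#' @param scope "all" (every element of `counts`), "autosomal", "whole", or
#'   an integer index vector into the backbone order.
#' @return Numeric vector of normalized depths over the scope, summing to 1e6.
#' @export
normalize_counts <- function(counts, panel = NULL, scope = "all") {
  x <- if (inherits(counts, "region_counts")) counts$counts else as.numeric(counts)
  idx <- if (is.numeric(scope)) as.integer(scope)
         else if (identical(scope, "all")) seq_along(x)
         else {
           if (is.null(panel)) stop("panel required for named scope '", scope, "'")
           backbone_scope(panel, match.arg(scope, c("autosomal", "whole")))
         }
  tot <- sum(x[idx])
  if (tot <= 0) stop("zero total count in normalization scope")
  x[idx] * 1e6 / tot
}

# Per-sample normalized-depth matrices (regions x samples) for a scope.
norm_matrix <- function(cohort, idx) {
  vapply(cohort, function(s) {
    tot <- sum(s$counts[idx])
    if (tot <= 0) stop("sample ", s$sample_id, " has zero counts in scope")
    s$counts[idx] * 1e6 / tot
  }, numeric(length(idx)))
}

row_sd <- function(m) {
  n <- ncol(m)
  rm_ <- rowMeans(m)
  sqrt(pmax(rowSums(m * m) - n * rm_^2, 0) / (n - 1))
}

# Isolated zero SDs (possible in noiseless simulation) are floored to the
# smallest positive SD so Z-values stay finite. A fully degenerate cohort
# (every SD zero) is kept as-is; scoring against it raises an error.
floor_sd <- function(s) {
  pos <- s[s > 0]
  if (!length(pos)) return(s)
  ifelse(s > 0, s, min(pos))
}

#' Build the euploid background database
#'
#' Computes, from a euploid reference cohort: per-region mean/SD of the
#' 1M-read normalized depths (autosomal scope for autosomes, whole-panel
#' scope for X/Y, the latter stratified by inferred fetal sex of the
#' background sample); per-chromosome mean/SD of the chromosome statistic
#' (mean normalized depth over the chromosome's regions); the chrY median
#' reference used for fetal sex inference; and the 95% background median
#' intervals used by the CNV caller's fourth criterion.
#'
#' @param cohort List of `region_counts` (>= 2 samples).
#' @param panel The `nipt_panel` the counts were produced on.
#' @param segment_background If TRUE (default) the background median interval
#'   is computed over HaarSeg segment medians of every background sample;
#'   the cheaper per-sample whole-median interval is always computed too.
#' @param max_scale,fdr_q HaarSeg parameters used for the background
#'   segmentation (see [haarseg_segment()]).
#' @return A `nipt_baseline` object.
#' @export
build_baseline <- function(cohort, panel, segment_background = TRUE,
                           max_scale = 5, fdr_q = 0.001) {
  if (length(cohort) < 2)
    stop("baseline requires at least 2 background samples")
  bb <- backbone_panel(panel)
  n_bb <- nrow(bb)
  if (any(vapply(cohort, function(s) length(s$counts), 0L) != n_bb))
    stop("cohort count vectors do not match the panel's backbone dimension")

  auto_idx <- backbone_scope(panel, "autosomal")
  whole_idx <- backbone_scope(panel, "whole")
  x_idx <- which(bb$chrom == "X")
  y_idx <- which(bb$chrom == "Y")

  m_auto <- norm_matrix(cohort, auto_idx)           # autosomal scope depths
  m_whole <- norm_matrix(cohort, whole_idx)         # whole-panel scope depths

  # --- fetal sex of background samples, from chrY median depth ------------
  unit <- 1e6 / length(whole_idx)
  y_median <- if (length(y_idx))
    apply(m_whole[y_idx, , drop = FALSE], 2, stats::median)
  else rep(0, length(cohort))
  is_male <- y_median > 0.02 * unit

  # --- autosomal region and chromosome statistics -------------------------
  auto_chrom <- bb$chrom[auto_idx]
  region_mean <- rowMeans(m_auto)
  region_sd <- floor_sd(row_sd(m_auto))
  chrom_stat <- function(m, chroms, cn) colMeans(m[chroms == cn, , drop = FALSE])
  chrom_auto <- do.call(rbind, lapply(AUTOSOMES, function(cn) {
    s <- chrom_stat(m_auto, auto_chrom, cn)
    data.frame(chrom = cn, n_regions = sum(auto_chrom == cn),
               mean = mean(s), sd = stats::sd(s), stringsAsFactors = FALSE)
  }))
  chrom_auto$sd <- floor_sd(chrom_auto$sd)

  # --- sex-chromosome statistics, stratified by fetal sex -----------------
  sex_chrom <- bb$chrom[whole_idx]
  stratum <- function(keep) {
    if (!length(c(x_idx, y_idx)) || sum(keep) < 2) return(NULL)
    m <- m_whole[, keep, drop = FALSE]
    sexpos <- c(x_idx, y_idx)
    ch <- do.call(rbind, lapply(intersect(c("X", "Y"), unique(sex_chrom)),
                                function(cn) {
      s <- chrom_stat(m, sex_chrom, cn)
      data.frame(chrom = cn, n_regions = sum(sex_chrom == cn),
                 mean = mean(s), sd = stats::sd(s), stringsAsFactors = FALSE)
    }))
    ch$sd[ch$sd == 0] <- min(c(ch$sd[ch$sd > 0], chrom_auto$sd))
    rm_ <- rowMeans(m[sexpos, , drop = FALSE])
    rs <- row_sd(m[sexpos, , drop = FALSE])
    rs <- ifelse(rs > 0, rs, min(c(rs[rs > 0], region_sd)))
    list(n = sum(keep), idx = sexpos, region_mean = rm_, region_sd = rs,
         chrom = ch)
  }
  strata <- list(XX = stratum(!is_male), XY = stratum(is_male))

  male_ref <- if (any(is_male)) mean(y_median[is_male]) else NA_real_

  baseline <- structure(list(
    panel_checksum = panel_checksum(panel),
    n_samples = length(cohort),
    backbone = bb[, c("chrom", "start", "end")],
    auto_idx = auto_idx, x_idx = x_idx, y_idx = y_idx,
    region_mean = region_mean, region_sd = region_sd,
    chrom_auto = chrom_auto, strata = strata,
    y_median_mean = if (any(is_male)) mean(y_median[is_male]) else 0,
    y_median_sd = if (sum(is_male) > 1) stats::sd(y_median[is_male]) else 0,
    male_y_reference = male_ref,
    background_is_male = is_male,
    median_interval_sample = NULL, median_interval_segment = NULL),
    class = "nipt_baseline")

  # --- background median intervals (CNV criterion 4) ----------------------
  if (all(region_sd == 0)) return(baseline)   # degenerate cohort: no Z scale
  sample_medians <- vapply(cohort, function(s) {
    z <- (normalize_counts(s$counts, scope = auto_idx) - region_mean) / region_sd
    stats::median(z)
  }, numeric(1))
  baseline$median_interval_sample <-
    unname(stats::quantile(sample_medians, c(0.025, 0.975), type = 7))

  if (segment_background) {
    seg_medians <- unlist(lapply(cohort, function(s) {
      zs <- region_z(s, baseline)
      unlist(lapply(split(zs$z, zs$chrom), function(z) {
        if (length(z) < 2) return(stats::median(z))
        segs <- haarseg_segment(z, max_scale = max_scale, fdr_q = fdr_q)
        segs$median_z
      }))
    }))
    baseline$median_interval_segment <-
      unname(stats::quantile(seg_medians, c(0.025, 0.975), type = 7))
  }
  baseline
}

#' @export
print.nipt_baseline <- function(x, ...) {
  cat(sprintf("<nipt_baseline> %d samples, %d backbone regions (%d autosomal)\n",
              x$n_samples, nrow(x$backbone), length(x$auto_idx)))
  cat(sprintf("  strata: XX n=%s, XY n=%s; background median interval [%.3f, %.3f]\n",
              x$strata$XX$n %||% 0, x$strata$XY$n %||% 0,
              x$median_interval_sample[1], x$median_interval_sample[2]))
  invisible(x)
}

check_baseline_sample <- function(sample, baseline) {
  if (length(sample$counts) != nrow(baseline$backbone))
    stop("sample does not match baseline panel dimensions")
}

#' Save / load a baseline bundle
#'
#' The baseline is serialized as a single JSON bundle carrying the panel
#' checksum; scoring functions refuse baselines built on a different panel.
#'
#' @param baseline A `nipt_baseline`.
#' @param path JSON path.
#' @return `path` / the restored `nipt_baseline`.
#' @export
save_baseline <- function(baseline, path) {
  jsonlite::write_json(unclass(baseline), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_baseline
#' @export
load_baseline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$backbone <- as.data.frame(x$backbone, stringsAsFactors = FALSE)
  x$chrom_auto <- as.data.frame(x$chrom_auto, stringsAsFactors = FALSE)
  for (s in names(x$strata))
    if (!is.null(x$strata[[s]]))
      x$strata[[s]]$chrom <- as.data.frame(x$strata[[s]]$chrom,
                                           stringsAsFactors = FALSE)
  structure(x, class = "nipt_baseline")
}
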