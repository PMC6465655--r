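#' Chromosome-level Z-values
#'
#' The chromosome statistic is the mean normalized depth over the
#' chromosome's backbone regions (autosomal-scope normalization for
#' autosomes, whole-panel scope for X and Y). Z is the deviation of that
#' statistic from the background mean in background-SD units. X is scored
#' against the XX-fetus background stratum (so a normal male fetus shows a
#' negative X Z of about -f/2 divided by the background CV); Y against the
#' XY stratum when available.
#'
#' @param sample A `region_counts` object.
#' @param baseline A `nipt_baseline`.
#' @return data.frame(chrom, statistic, z) over 1-22, X, Y.
#' @export
chromosome_z <- function(sample, baseline) {
  check_baseline_sample(sample, baseline)
  bb_chrom <- baseline$backbone$chrom
  d_auto <- normalize_counts(sample$counts, scope = baseline$auto_idx)
  auto_chrom <- bb_chrom[baseline$auto_idx]
  out <- baseline$chrom_auto
  if (any(out$sd == 0))
    stop("background chromosome SD is zero even after flooring; ",
         "the cohort is degenerate")
  stat <- vapply(out$chrom, function(cn) mean(d_auto[auto_chrom == cn]),
                 numeric(1))
  out$statistic <- stat
  out$z <- (stat - out$mean) / out$sd

  d_whole <- normalize_counts(sample$counts,
                              scope = seq_len(nrow(baseline$backbone)))
  sex_row <- function(cn, stratum) {
    st <- baseline$strata[[stratum]] %||% baseline$strata$XX %||% baseline$strata$XY
    idx <- if (cn == "X") baseline$x_idx else baseline$y_idx
    if (!length(idx) || is.null(st)) return(NULL)
    ch <- st$chrom[st$chrom$chrom == cn, ]
    if (!nrow(ch)) return(NULL)
    if (ch$sd == 0)
      stop("background chromosome SD is zero even after flooring on chr", cn)
    stat <- mean(d_whole[idx])
    data.frame(chrom = cn, n_regions = length(idx), mean = ch$mean, sd = ch$sd,
               statistic = stat, z = (stat - ch$mean) / ch$sd,
               stringsAsFactors = FALSE)
  }
  out <- rbind(out, sex_row("X", "XX"), sex_row("Y", "XY"))
  rownames(out) <- NULL
  out[, c("chrom", "statistic", "z")]
}

#' Call autosomal aneuploidies from chromosome Z-values
#'
#' Trisomy is called where z >= z_cut, monosomy where z <= -z_cut.
#'
#' @param zs data.frame(chrom, z) covering the 22 autosomes (extra rows are
#'   ignored), as returned by [chromosome_z()].
#' @param z_cut Z threshold (default 3, the standard NIPT cut).
#' @return data.frame(chrom, state) with state trisomy/monosomy/euploid.
#' @export
call_autosomal_aneuploidy <- function(zs, z_cut = 3) {
  zs <- zs[zs$chrom %in% AUTOSOMES, , drop = FALSE]
  if (!setequal(zs$chrom, AUTOSOMES))
    stop("chromosome Z table must cover all 22 autosomes")
  state <- ifelse(zs$z >= z_cut, "trisomy",
                  ifelse(zs$z <= -z_cut, "monosomy", "euploid"))
  data.frame(chrom = zs$chrom, z = zs$z, state = state,
             stringsAsFactors = FALSE)
}

#' Infer fetal sex and sex karyotype
#'
#' The fetus is called male when both the median and the mean normalized
#' depth over the chrY backbone regions exceed `male_frac` of the full male
#' Y dose estimated from the XY background samples (robust down to fetal
#' fractions of about male_frac x the background mean). The sex karyotype is
#' refined with the X Z-value against the XX-fetus background stratum:
#' a male-level Y signal with XX-level X dose is 47,XXY; an X loss
#' (z <= -x_cut) without Y signal is 45,X; inconsistent signals (e.g. a
#' strong X gain, or disagreeing Y median/mean) are flagged "other".
#'
#' @param sample A `region_counts`.
#' @param baseline A `nipt_baseline`.
#' @param male_frac Fraction of the male Y reference dose required to call a
#'   male fetus (default 0.25).
#' @param x_cut X Z threshold for X-loss flagging (default 3).
#' @return list(fetal_sex, sex_karyotype, y_median, y_mean, y_threshold, x_z).
#' @export
infer_fetal_sex <- function(sample, baseline, male_frac = 0.25, x_cut = 3) {
  check_baseline_sample(sample, baseline)
  whole_idx <- seq_len(nrow(baseline$backbone))
  d <- normalize_counts(sample$counts, scope = whole_idx)
  y <- d[baseline$y_idx]
  unit <- 1e6 / length(whole_idx)
  thr <- if (!is.na(baseline$male_y_reference))
    male_frac * baseline$male_y_reference else 0.02 * unit
  y_med <- stats::median(y); y_mean <- mean(y)
  y_signal_med <- y_med >= thr
  y_signal_mean <- y_mean >= thr
  y_signal <- y_signal_med && y_signal_mean

  cz <- chromosome_z(sample, baseline)
  x_z <- cz$z[cz$chrom == "X"]
  if (!length(x_z)) x_z <- 0          # panel without chrX regions
  x_low <- x_z <= -x_cut
  x_high <- x_z >= x_cut

  karyotype <- if (y_signal_med != y_signal_mean) "other"
    else if (y_signal && x_low) "XY"
    else if (y_signal && x_high) "other"
    else if (y_signal) "XXY"
    else if (x_low) "X0"
    else if (x_high) "other"
    else "XX"

  list(fetal_sex = if (y_signal) "XY" else "XX",
       sex_karyotype = karyotype,
       y_median = y_med, y_mean = y_mean, y_threshold = thr, x_z = x_z)
}

#' Full aneuploidy screen of one sample
#'
#' Combines [chromosome_z()], [call_autosomal_aneuploidy()] and
#' [infer_fetal_sex()] into one report.
#'
#' @inheritParams infer_fetal_sex
#' @param z_cut Autosomal Z threshold.
#' @return An `aneuploidy_call`: list(sample_id, chrom_z, calls, fetal_sex,
#'   sex_karyotype, result) where `result` is the compact Table-1-style label
#'   ("T21", "X0", "XXY", ... or "euploid").
#' @export
call_aneuploidy <- function(sample, baseline, z_cut = 3, x_cut = 3,
                            male_frac = 0.25) {
  cz <- chromosome_z(sample, baseline)
  calls <- call_autosomal_aneuploidy(cz, z_cut = z_cut)
  sex <- infer_fetal_sex(sample, baseline, male_frac = male_frac, x_cut = x_cut)
  pos <- calls[calls$state != "euploid", , drop = FALSE]
  labels <- character(0)
  if (nrow(pos))
    labels <- paste0(ifelse(pos$state == "trisomy", "T", "M"), pos$chrom)
  if (sex$sex_karyotype %in% c("X0", "XXY", "other"))
    labels <- c(labels, sex$sex_karyotype)
  structure(list(sample_id = sample$sample_id, chrom_z = cz, calls = calls,
                 fetal_sex = sex$fetal_sex, sex_karyotype = sex$sex_karyotype,
                 sex_detail = sex,
                 result = if (length(labels)) paste(labels, collapse = "+")
                          else "euploid"),
            class = "aneuploidy_call")
}

#' @export
print.aneuploidy_call <- function(x, ...) {
  cat(sprintf("<aneuploidy_call> %s: %s (fetal sex %s, karyotype %s)\n",
              x$sample_id, x$result, x$fetal_sex, x$sex_karyotype))
  top <- x$chrom_z[order(-abs(x$chrom_z$z)), ][1:3, ]
  cat("  largest |z|:",
      paste(sprintf("chr%s %.2f", top$chrom, top$z), collapse = ", "), "\n")
  invisible(x)
}

#' Write a per-chromosome aneuploidy report TSV
#'
#' One row per chromosome (statistic, z, state) plus a trailing summary row,
#' mirroring the layout of a per-sample clinical report.
#'
#' @param call An `aneuploidy_call`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_aneuploidy_tsv <- function(call, path) {
  df <- merge(call$chrom_z, call$calls[, c("chrom", "state")],
              by = "chrom", all.x = TRUE, sort = FALSE)
  df$state[is.na(df$state)] <- ""
  df <- df[order(chrom_factor(df$chrom)), ]
  df <- rbind(df, data.frame(chrom = "result", statistic = NA, z = NA,
                             state = call$result, stringsAsFactors = FALSE))
  write_tsv(df, path)
}
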