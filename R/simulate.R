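GENOTYPES <- c("AA", "AB", "BB")

#' Ground-truth description of a simulated maternal-fetal sample
#'
#' Records everything the simulator needs about one plasma sample: the fetal
#' fraction, the fetal sex karyotype, whole-chromosome aneuploidies, fetal
#' CNVs, and per-locus maternal/fetal genotypes at hotspot loci. Fetal
#' genotypes must share at least one allele with the maternal genotype
#' (maternal transmission); the other allele is paternal.
#'
#' @param fetal_fraction Fetal fraction in (0, 1).
#' @param sex_karyotype Fetal sex karyotype: "XX", "XY", "X0" or "XXY".
#' @param aneuploidies NULL or data.frame(chrom, state) with state "trisomy"
#'   or "monosomy" on autosomes.
#' @param cnvs NULL or data.frame(chrom, start, end, copy_delta) with
#'   copy_delta +1 (fetal single-copy gain) or -1 (loss), coordinates in bp.
#' @param maternal_genotypes,fetal_genotypes Named character vectors
#'   (locus_id -> "AA"/"AB"/"BB"); must share names.
#' @param sample_id Sample label.
#' @return A `sample_truth` object.
#' @export
sample_truth <- function(fetal_fraction, sex_karyotype = "XX",
                         aneuploidies = NULL, cnvs = NULL,
                         maternal_genotypes = NULL, fetal_genotypes = NULL,
                         sample_id = "sample") {
  if (!(fetal_fraction > 0 && fetal_fraction < 1))
    stop("fetal_fraction must lie strictly between 0 and 1")
  sex_karyotype <- match.arg(sex_karyotype, c("XX", "XY", "X0", "XXY"))
  if (!is.null(aneuploidies)) {
    aneuploidies <- as.data.frame(aneuploidies, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "state") %in% names(aneuploidies)))
    aneuploidies$chrom <- as.character(aneuploidies$chrom)
    if (!all(aneuploidies$chrom %in% AUTOSOMES))
      stop("aneuploidies must name autosomes; sex karyotypes go in sex_karyotype")
    if (!all(aneuploidies$state %in% c("trisomy", "monosomy")))
      stop("aneuploidy state must be 'trisomy' or 'monosomy'")
  }
  if (!is.null(cnvs)) {
    cnvs <- as.data.frame(cnvs, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end", "copy_delta") %in% names(cnvs)))
    cnvs$chrom <- as.character(cnvs$chrom)
    if (any(cnvs$end <= cnvs$start)) stop("CNV intervals must have end > start")
    if (!all(cnvs$copy_delta %in% c(-1, 1)))
      stop("copy_delta must be -1 or +1 (single fetal copy loss/gain)")
  }
  if (!is.null(maternal_genotypes) || !is.null(fetal_genotypes)) {
    if (is.null(maternal_genotypes) || is.null(fetal_genotypes) ||
        !setequal(names(maternal_genotypes), names(fetal_genotypes)))
      stop("maternal and fetal genotypes must cover the same loci")
    fetal_genotypes <- fetal_genotypes[names(maternal_genotypes)]
    if (!all(maternal_genotypes %in% GENOTYPES) ||
        !all(fetal_genotypes %in% GENOTYPES))
      stop("genotypes must be AA, AB or BB")
    bad <- !mendelian_ok(maternal_genotypes, fetal_genotypes)
    if (any(bad))
      stop("non-Mendelian mother-fetus genotype pair at locus ",
           paste(names(maternal_genotypes)[bad], collapse = ", "),
           " (fetus must inherit one maternal allele)")
  }
  structure(list(sample_id = sample_id, fetal_fraction = fetal_fraction,
                 fetal_sex = if (sex_karyotype %in% c("XY", "XXY")) "XY" else "XX",
                 sex_karyotype = sex_karyotype,
                 aneuploidies = aneuploidies, cnvs = cnvs,
                 maternal_genotypes = maternal_genotypes,
                 fetal_genotypes = fetal_genotypes),
            class = "sample_truth")
}

mendelian_ok <- function(maternal, fetal) {
  # fetus must carry at least one maternal allele
  !(maternal == "AA" & fetal == "BB") & !(maternal == "BB" & fetal == "AA")
}

#' @export
print.sample_truth <- function(x, ...) {
  cat(sprintf("<sample_truth> %s: FF=%.3f, karyotype %s, %d aneuploidies, %d CNVs, %d loci\n",
              x$sample_id, x$fetal_fraction, x$sex_karyotype,
              NROW(x$aneuploidies), NROW(x$cnvs),
              length(x$maternal_genotypes)))
  invisible(x)
}

# Expected relative dose per backbone region under the copy-dose model:
# a fetal single-copy gain multiplies a region's dose by (1 + f/2), a loss
# by (1 - f/2); chrY carries f/2 of an autosomal dose for a male fetus and
# 0 for a female fetus.
region_doses <- function(panel, truth) {
  bb <- backbone_panel(panel)
  f <- truth$fetal_fraction
  dose <- rep(1, nrow(bb))
  kx <- truth$sex_karyotype
  dose[bb$chrom == "X"] <- switch(kx, XX = 1, XXY = 1,
                                  XY = 1 - f / 2, X0 = 1 - f / 2)
  dose[bb$chrom == "Y"] <- switch(kx, XX = 0, X0 = 0,
                                  XY = f / 2, XXY = f / 2)
  if (!is.null(truth$aneuploidies)) {
    for (i in seq_len(nrow(truth$aneuploidies))) {
      cn <- truth$aneuploidies$chrom[i]
      if (!any(bb$chrom == cn))
        stop("aneuploidy on chromosome absent from panel: ", cn)
      fac <- if (truth$aneuploidies$state[i] == "trisomy") 1 + f / 2 else 1 - f / 2
      dose[bb$chrom == cn] <- dose[bb$chrom == cn] * fac
    }
  }
  if (!is.null(truth$cnvs)) {
    for (i in seq_len(nrow(truth$cnvs))) {
      cn <- truth$cnvs$chrom[i]
      if (!any(bb$chrom == cn))
        stop("CNV on chromosome absent from panel: ", cn)
      hit <- bb$chrom == cn & bb$start < truth$cnvs$end[i] &
             bb$end > truth$cnvs$start[i]
      fac <- if (truth$cnvs$copy_delta[i] > 0) 1 + f / 2 else 1 - f / 2
      dose[hit] <- dose[hit] * fac
    }
  }
  dose
}

new_region_counts <- function(sample_id, counts, total_reads) {
  structure(list(sample_id = sample_id, counts = as.numeric(counts),
                 total_reads = total_reads),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("<region_counts> %s: %d regions, %s reads\n", x$sample_id,
              length(x$counts), format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Simulate backbone region read counts for one sample
#'
#' Counts are multinomial over the backbone regions with expected proportions
#' proportional to (uniform capture weight) x (copy dose implied by the
#' sample truth). With `dispersion` > 0, region weights are first perturbed
#' by independent Gamma noise of unit mean and variance `dispersion`
#' (a Dirichlet-multinomial with per-region concentration 1/dispersion),
#' emulating residual inter-sample capture variability.
#'
#' @param panel A `nipt_panel`.
#' @param truth A `sample_truth`.
#' @param total_reads Total unique read count of the sample.
#' @param dispersion Overdispersion (squared CV of region weights); 0 gives
#'   a pure multinomial.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A `region_counts` object (counts in panel backbone order).
#' @export
simulate_region_counts <- function(panel, truth, total_reads = 2e6,
                                   dispersion = 2.5e-4, seed = 1) {
  stopifnot(total_reads > 0, dispersion >= 0)
  w <- region_doses(panel, truth)
  with_seed(seed, {
    if (dispersion > 0) {
      pos <- w > 0
      g <- numeric(length(w))
      g[pos] <- w[pos] * stats::rgamma(sum(pos), shape = 1 / dispersion,
                                       rate = 1 / dispersion)
      w <- g
    }
    counts <- stats::rmultinom(1, size = total_reads, prob = w / sum(w))[, 1]
  })
  new_region_counts(truth$sample_id, counts, total_reads)
}

#' Simulate a euploid reference cohort
#'
#' Generates `n_samples` euploid pregnancies with fetal fractions drawn
#' uniformly from `ff_range` and random fetal sex (unless fixed), each
#' simulated with an independent child seed of `seed`.
#'
#' @param panel A `nipt_panel`.
#' @param n_samples Number of background samples (>= 2; the downstream
#'   baseline needs a standard deviation).
#' @param total_reads,dispersion Passed to [simulate_region_counts()].
#' @param seed Master seed.
#' @param ff_range Fetal-fraction range sampled uniformly.
#' @param fetal_sex NULL for random 1:1 sex, or "XX"/"XY" to fix it.
#' @return List of `region_counts`; the generating `sample_truth` objects are
#'   attached as attribute "truths".
#' @export
simulate_reference_cohort <- function(panel, n_samples = 68, total_reads = 2e6,
                                      dispersion = 2.5e-4, seed = 1,
                                      ff_range = c(0.16, 0.25),
                                      fetal_sex = NULL) {
  if (n_samples < 2)
    stop("a reference cohort needs at least 2 samples (SD undefined otherwise)")
  cfg <- with_seed(seed, {
    list(ff = stats::runif(n_samples, ff_range[1], ff_range[2]),
         sex = if (is.null(fetal_sex))
                 sample(c("XX", "XY"), n_samples, replace = TRUE)
               else rep(fetal_sex, n_samples),
         seeds = sample.int(.Machine$integer.max - 1L, n_samples))
  })
  truths <- lapply(seq_len(n_samples), function(i) {
    sample_truth(cfg$ff[i], sex_karyotype = cfg$sex[i],
                 sample_id = sprintf("bg%03d", i))
  })
  cohort <- lapply(seq_len(n_samples), function(i) {
    simulate_region_counts(panel, truths[[i]], total_reads = total_reads,
                           dispersion = dispersion, seed = cfg$seeds[i])
  })
  attr(cohort, "truths") <- truths
  cohort
}

#' Simulate allele pileups at hotspot loci
#'
#' For each locus in the truth genotype maps, depth is Poisson around
#' `mean_depth` and the alt count is binomial with success probability equal
#' to the expected mixture B-allele fraction of the mother-fetus genotype
#' pair at the sample's fetal fraction, clamped to
#' \[error_rate, 1 - error_rate\] to absorb sequencing error.
#'
#' @param truth A `sample_truth` with per-locus genotypes.
#' @param mean_depth Mean sequencing depth per locus.
#' @param error_rate Per-base error floor in \[0, 0.5).
#' @param seed Integer seed.
#' @return data.frame(locus_id, ref, alt, ref_count, alt_count).
#' @export
simulate_pileups <- function(truth, mean_depth = 200, error_rate = 0.005,
                             seed = 1) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (is.null(truth$maternal_genotypes))
    stop("sample truth carries no hotspot genotypes")
  loci <- names(truth$maternal_genotypes)
  combo <- paste0(truth$maternal_genotypes, truth$fetal_genotypes)
  p <- vapply(combo, expected_alt_fraction, numeric(1),
              f = truth$fetal_fraction)
  p <- pmin(pmax(p, error_rate), 1 - error_rate)
  with_seed(seed, {
    depth <- stats::rpois(length(loci), mean_depth)
    alt <- stats::rbinom(length(loci), size = depth, prob = p)
  })
  data.frame(locus_id = loci, ref = "A", alt = "B",
             ref_count = depth - alt, alt_count = alt,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Draw mother-fetus genotypes for a set of loci
#'
#' Maternal genotypes are Hardy-Weinberg at each locus's population B-allele
#' frequency; the fetus inherits one maternal allele at random and one
#' paternal allele drawn from the same population frequency. Specific loci
#' can be forced to a given mother/fetus pair (for case configurations).
#'
#' @param loci data.frame with columns locus_id and pop_b_freq (see
#'   [default_locus_metadata()]).
#' @param seed Integer seed.
#' @param force NULL or named list locus_id -> c(maternal, fetal).
#' @return list(maternal, fetal): named genotype vectors.
#' @export
simulate_truth_genotypes <- function(loci, seed = 1, force = NULL) {
  q <- loci$pop_b_freq
  with_seed(seed, {
    m_b <- stats::rbinom(nrow(loci), 2, q)               # maternal B-allele count
    transmitted <- stats::rbinom(nrow(loci), 1, m_b / 2) # maternal allele to fetus
    paternal <- stats::rbinom(nrow(loci), 1, q)
  })
  f_b <- transmitted + paternal
  maternal <- GENOTYPES[m_b + 1]
  fetal <- GENOTYPES[f_b + 1]
  names(maternal) <- names(fetal) <- loci$locus_id
  for (id in names(force %||% list())) {
    maternal[id] <- force[[id]][1]
    fetal[id] <- force[[id]][2]
  }
  list(maternal = maternal, fetal = fetal)
}

#' Write/read a cohort count matrix as TSV
#'
#' Rows are backbone regions labelled `chrom:start-end`, columns are samples.
#'
#' @param cohort List of `region_counts` (or a single one).
#' @param panel The panel the counts were simulated from.
#' @param path TSV path.
#' @return `path` (write) / list of `region_counts` (read).
#' @export
write_counts_tsv <- function(cohort, panel, path) {
  if (inherits(cohort, "region_counts")) cohort <- list(cohort)
  bb <- backbone_panel(panel)
  m <- sapply(cohort, function(s) s$counts)
  colnames(m) <- vapply(cohort, function(s) s$sample_id, character(1))
  df <- data.frame(region = sprintf("%s:%.0f-%.0f", bb$chrom, bb$start, bb$end),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  lapply(names(df)[-1], function(id) {
    new_region_counts(id, df[[id]], sum(df[[id]]))
  })
}
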