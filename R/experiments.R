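#' Simulation-twin validation experiments
#'
#' These functions re-create, on synthetic data, the three validation
#' experiments of the assay's clinical evaluation: the aneuploidy cohort
#' (seven aneuploid pregnancies against a 68-sample euploid background),
#' the CNV cohort (three fetal duplications of at least 20 Mb), and the
#' single-gene cohort (twelve variant-carrying plus ten variant-free
#' pregnancies). Each experiment simulates the bundled case configurations
#' at their recorded fetal fractions and depths, runs the corresponding
#' screening arm end to end, and reports detection/accuracy rates. Rates are
#' Monte-Carlo estimates over `replicates` independently simulated case
#' cohorts (the background is simulated once per experiment).
#'
#' @param seed Master seed; every random draw derives from it.
#' @param replicates Number of replicate case cohorts.
#' @param n_background Background cohort size.
#' @param total_reads Unique reads per sample.
#' @param dispersion Simulator overdispersion.
#' @param panel A `nipt_panel` (defaults to [paper_panel()]).
#' @param z_cut Autosomal Z threshold.
#' @param error_rate Sequencing error floor for pileups.
#' @param n_controls Number of variant-free samples per replicate.
#' @param n_common Number of common SNP loci powering fetal-fraction
#'   estimation.
#' @return A list with the per-case results and the headline rate(s) in
#'   percent; see each function's value section.
#' @name twin_experiments
NULL

#' @rdname twin_experiments
#' @export
twin_aneuploidy <- function(seed = 1, replicates = 3, n_background = 68,
                            total_reads = 2e6, dispersion = 2.5e-4,
                            panel = paper_panel(), z_cut = 3) {
  seeds <- child_seeds(seed, 2)
  cohort <- simulate_reference_cohort(panel, n_samples = n_background,
                                      total_reads = total_reads,
                                      dispersion = dispersion, seed = seeds[1])
  baseline <- build_baseline(cohort, panel, segment_background = FALSE)
  cases <- demo_aneuploidy_cases()
  cseeds <- matrix(child_seeds(seeds[2], replicates * nrow(cases)),
                   nrow = replicates)
  rows <- list()
  for (r in seq_len(replicates)) for (i in seq_len(nrow(cases))) {
    truth <- aneuploidy_case_truth(cases[i, ])
    s <- simulate_region_counts(panel, truth, total_reads = total_reads,
                                dispersion = dispersion, seed = cseeds[r, i])
    call <- call_aneuploidy(s, baseline, z_cut = z_cut)
    detected <- if (!is.na(cases$chrom[i])) {
      row <- call$calls[call$calls$chrom == cases$chrom[i], ]
      row$state == "trisomy"
    } else call$sex_karyotype == cases$sex_karyotype[i]
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, sample_id = cases$sample_id[i],
      karyotype = cases$karyotype[i], result = call$result,
      detected = detected, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  list(cases = res, detection_rate = 100 * mean(res$detected),
       baseline = baseline)
}

#' @rdname twin_experiments
#' @export
twin_cnv <- function(seed = 1, replicates = 3, n_background = 68,
                     total_reads = 1e7, dispersion = 2.5e-4,
                     panel = paper_panel()) {
  seeds <- child_seeds(seed, 2)
  cohort <- simulate_reference_cohort(panel, n_samples = n_background,
                                      total_reads = total_reads,
                                      dispersion = dispersion, seed = seeds[1])
  baseline <- build_baseline(cohort, panel)
  truths <- cnv_case_truths()
  bb <- backbone_panel(panel)
  cseeds <- matrix(child_seeds(seeds[2], replicates * length(truths)),
                   nrow = replicates)
  rows <- list()
  for (r in seq_len(replicates)) for (i in seq_along(truths)) {
    tr <- truths[[i]]
    s <- simulate_region_counts(panel, tr, total_reads = total_reads,
                                dispersion = dispersion, seed = cseeds[r, i])
    scr <- call_sample_cnvs(s, baseline, panel = panel)
    for (cn in unique(tr$cnvs$chrom)) {
      # contiguous same-direction events merge; judge against their union
      lo <- min(tr$cnvs$start[tr$cnvs$chrom == cn])
      hi <- max(tr$cnvs$end[tr$cnvs$chrom == cn])
      idx <- which(bb$chrom == cn & bb$start < hi & bb$end > lo)
      spacing <- stats::median(diff(bb$start[bb$chrom == cn]))
      calls <- scr$calls[scr$calls$chrom == cn & scr$calls$direction == "dup", ]
      detected <- nrow(calls) > 0
      boundary_ok <- detected &&
        abs(calls$start[1] - bb$start[idx[1]]) <= spacing &&
        abs(calls$end[1] - bb$end[idx[length(idx)]]) <= spacing
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, sample_id = tr$sample_id, chrom = cn,
        truth_size = hi - lo,
        called_size = if (detected) calls$size[1] else NA_real_,
        median_z = if (detected) calls$median_z[1] else NA_real_,
        detected = detected, boundary_ok = boundary_ok,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  list(events = res, detection_rate = 100 * mean(res$detected),
       boundary_rate = 100 * mean(res$boundary_ok))
}

#' @rdname twin_experiments
#' @export
twin_snv <- function(seed = 1, replicates = 5, n_controls = 10,
                     error_rate = 0.005, n_common = 200) {
  loci <- default_locus_metadata(n_common = n_common)
  path_loci <- loci$locus_id[!is.na(loci$disease)]
  cases <- demo_snv_cases()
  seeds <- child_seeds(seed, replicates)
  rows <- list()
  for (r in seq_len(replicates)) {
    ss <- child_seeds(seeds[r], 2 * (nrow(cases) + n_controls) + 1)
    ctl_ff <- with_seed(ss[length(ss)], stats::runif(n_controls, 0.18, 0.25))
    ctl_depth <- with_seed(ss[length(ss)], round(stats::runif(n_controls, 130, 305)))
    for (i in seq_len(nrow(cases) + n_controls)) {
      if (i <= nrow(cases)) {
        truth <- snv_case_truth(cases[i, ], loci = loci, seed = ss[2 * i - 1])
        depth <- cases$depth[i]
        id <- cases$sample_id[i]
      } else {
        j <- i - nrow(cases)
        truth <- snv_control_truth(ctl_ff[j], loci = loci, seed = ss[2 * i - 1],
                                   sample_id = sprintf("control%02d", j))
        depth <- ctl_depth[j]
        id <- truth$sample_id
      }
      pile <- simulate_pileups(truth, mean_depth = depth,
                               error_rate = error_rate, seed = ss[2 * i])
      scr <- screen_single_gene(pile, loci = loci, error_rate = error_rate)
      truth_set <- intersect(
        names(truth$fetal_genotypes)[truth$fetal_genotypes %in% c("AB", "BB")],
        path_loci)
      called_set <- scr$variants$loci$locus_id[scr$variants$loci$reported != "ND"]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, sample_id = id, carrier = i <= nrow(cases),
        ff_true = truth$fetal_fraction, ff_est = scr$ff$f,
        n_truth = length(truth_set),
        exact_match = setequal(truth_set, called_set),
        all_detected = all(truth_set %in% called_set),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  list(samples = res,
       accuracy = 100 * mean(res$exact_match),
       sensitivity = 100 * mean(res$all_detected[res$carrier]),
       specificity = 100 * mean(res$exact_match[!res$carrier]))
}

#' Locus-level genotype concordance experiment
#'
#' Simulates pileups for loci spanning all seven pseudo-tetraploid classes
#' in equal numbers, genotypes them at the known fetal fraction with the
#' default Hardy-Weinberg model prior at the common-SNP B-allele frequency,
#' and reports overall concordance plus concordance pooled over the three
#' fetal-fraction-uninformative classes (AAAA, ABAB, BBBB).
#'
#' @param seed Master seed.
#' @param n_per_combo Loci per class.
#' @param f Fetal fraction.
#' @param depth Mean depth.
#' @param error_rate Error floor.
#' @param pop_b_freq Population B-allele frequency for the model prior.
#' @return list(confusion, overall, homozygote_like) (percent).
#' @export
ptg_concordance <- function(seed = 1, n_per_combo = 150, f = 0.20,
                            depth = 200, error_rate = 0.005,
                            pop_b_freq = 0.30) {
  combos <- rep(pseudo_tetraploid_space(), each = n_per_combo)
  mat <- maternal_part(combos)
  fet <- fetal_part(combos)
  truth <- sample_truth(f, maternal_genotypes = stats::setNames(mat, seq_along(mat)),
                        fetal_genotypes = stats::setNames(fet, seq_along(fet)),
                        sample_id = "concordance")
  pile <- simulate_pileups(truth, mean_depth = depth, error_rate = error_rate,
                           seed = seed)
  calls <- map_genotypes(pile, f = f,
                         prior = hwe_prior(rep(pop_b_freq, length(combos))),
                         error_rate = error_rate)
  ok <- calls$map_combo == combos
  steady <- combos %in% c("AAAA", "ABAB", "BBBB")
  list(confusion = table(truth = combos, call = calls$map_combo),
       overall = 100 * mean(ok),
       homozygote_like = 100 * mean(ok[steady]))
}

#' Euploid false-positive experiment
#'
#' Simulates euploid test pregnancies against an independently simulated
#' background and reports the fraction of samples with any autosomal
#' |Z| >= z_cut (i.e. samples that would receive a false aneuploidy call).
#'
#' @inheritParams twin_aneuploidy
#' @param n_test Number of euploid test samples.
#' @return list(per_sample, fpr) with fpr in percent.
#' @export
euploid_fpr <- function(seed = 1, n_test = 200, n_background = 68,
                        total_reads = 2e6, dispersion = 2.5e-4,
                        panel = paper_panel(), z_cut = 3) {
  seeds <- child_seeds(seed, 2)
  cohort <- simulate_reference_cohort(panel, n_samples = n_background,
                                      total_reads = total_reads,
                                      dispersion = dispersion, seed = seeds[1])
  baseline <- build_baseline(cohort, panel, segment_background = FALSE)
  test <- simulate_reference_cohort(panel, n_samples = n_test,
                                    total_reads = total_reads,
                                    dispersion = dispersion, seed = seeds[2])
  any_hit <- vapply(test, function(s) {
    cz <- chromosome_z(s, baseline)
    any(abs(cz$z[cz$chrom %in% AUTOSOMES]) >= z_cut)
  }, logical(1))
  list(per_sample = any_hit, fpr = 100 * mean(any_hit))
}
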