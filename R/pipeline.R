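default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "nipt3_run",
    panel = list(source = "paper"),      # "paper", "small", or a BED path
    cohort = list(n_samples = 68, total_reads = 2e6, dispersion = 2.5e-4,
                  ff_range = c(0.16, 0.25)),
    thresholds = list(z_cut = 3, x_cut = 3, male_frac = 0.25,
                      max_scale = 5, fdr_q = 0.001,
                      min_regions = 20, min_span = 1e7,
                      mean_z_range = c(-0.7, 0.7), median_z_range = c(-2, 2),
                      tolerance = 0.001, error_rate = 0.005, f_init = 0.10),
    snv = list(mean_depth = 200, n_common = 200, common_freq = 0.30),
    cases = list(aneuploidy = TRUE, cnv = TRUE, snv = TRUE, n_snv_controls = 2))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration and completes it with the documented defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides Optional named list applied on top (CLI flags).
#' @return A complete configuration list.
#' @export
load_pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_panel <- function(cfg) {
  src <- cfg$panel$source %||% "paper"
  if (src == "paper") paper_panel()
  else if (src == "small")
    generate_panel_layout(
      chrom_sizes = round(default_chrom_sizes() / 40),
      n_backbone = cfg$panel$n_backbone %||% 600,
      backbone_length = 100,
      hotspot_spec = default_hotspot_spec_small(),
      fixed_counts = c(X = 30, Y = 8))
  else load_panel(src)
}

# Scaled-down hotspot spec for fast demonstration runs: 10 windows per gene
# anchored at the scaled gene locus, 500 bp apart.
default_hotspot_spec_small <- function() {
  lapply(default_hotspot_spec(), function(w) {
    w <- utils::head(w, 10)
    len <- w$end - w$start
    w$start <- round(min(w$start) / 40) + (seq_len(nrow(w)) - 1) * 500
    w$end <- w$start + len
    w
  })
}

#' Run the full three-arm pipeline on a simulated demonstration cohort
#'
#' Generates (or loads) the panel, simulates the euploid background and the
#' bundled case samples, builds the baseline, and runs all three screening
#' arms, writing: the panel BED, the baseline JSON bundle, per-sample
#' aneuploidy TSVs, CNV TSV/BED, variant TSV/VCF, and a JSON run manifest
#' (seed, thresholds, config hash). Re-running with the same configuration
#' reproduces the outputs.
#'
#' @param config A configuration list ([load_pipeline_config()]), or a YAML
#'   path.
#' @return Invisibly, list(out_dir, manifest, results).
#' @export
run_pipeline <- function(config = load_pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (d in c("aneuploidy", "cnv", "snv"))
    dir.create(file.path(out, d), showWarnings = FALSE)
  th <- cfg$thresholds
  seeds <- child_seeds(cfg$seed, 6)

  panel <- pipeline_panel(cfg)
  write_panel(panel, file.path(out, "panel.bed"))

  cohort <- simulate_reference_cohort(panel,
                                      n_samples = cfg$cohort$n_samples,
                                      total_reads = cfg$cohort$total_reads,
                                      dispersion = cfg$cohort$dispersion,
                                      seed = seeds[1],
                                      ff_range = cfg$cohort$ff_range)
  write_counts_tsv(cohort, panel, file.path(out, "background_counts.tsv"))
  baseline <- build_baseline(cohort, panel,
                             max_scale = th$max_scale, fdr_q = th$fdr_q)
  save_baseline(baseline, file.path(out, "baseline.json"))

  results <- list()

  if (isTRUE(cfg$cases$aneuploidy)) {
    cases <- demo_aneuploidy_cases()
    cseeds <- child_seeds(seeds[2], nrow(cases))
    results$aneuploidy <- lapply(seq_len(nrow(cases)), function(i) {
      truth <- aneuploidy_case_truth(cases[i, ])
      s <- simulate_region_counts(panel, truth,
                                  total_reads = cfg$cohort$total_reads,
                                  dispersion = cfg$cohort$dispersion,
                                  seed = cseeds[i])
      call <- call_aneuploidy(s, baseline, z_cut = th$z_cut, x_cut = th$x_cut,
                              male_frac = th$male_frac)
      write_aneuploidy_tsv(call, file.path(out, "aneuploidy",
                                           paste0(truth$sample_id, ".tsv")))
      call
    })
  }

  if (isTRUE(cfg$cases$cnv)) {
    truths <- cnv_case_truths()
    cseeds <- child_seeds(seeds[3], length(truths))
    results$cnv <- lapply(seq_along(truths), function(i) {
      s <- simulate_region_counts(panel, truths[[i]],
                                  total_reads = cfg$cohort$total_reads,
                                  dispersion = cfg$cohort$dispersion,
                                  seed = cseeds[i])
      scr <- call_sample_cnvs(s, baseline, panel = panel,
                              max_scale = th$max_scale, fdr_q = th$fdr_q,
                              min_regions = th$min_regions,
                              min_span = th$min_span,
                              mean_z_range = th$mean_z_range,
                              median_z_range = th$median_z_range)
      write_cnv_tsv(scr$calls, file.path(out, "cnv",
                                         paste0(s$sample_id, ".tsv")))
      write_cnv_bed(scr$calls, file.path(out, "cnv",
                                         paste0(s$sample_id, ".bed")))
      scr
    })
  }

  if (isTRUE(cfg$cases$snv)) {
    loci <- default_locus_metadata(n_common = cfg$snv$n_common,
                                   common_freq = cfg$snv$common_freq)
    cases <- demo_snv_cases()
    cseeds <- child_seeds(seeds[4], nrow(cases) + cfg$cases$n_snv_controls)
    run_one <- function(truth, depth, seed) {
      pile <- simulate_pileups(truth, mean_depth = depth,
                               error_rate = th$error_rate, seed = seed)
      scr <- screen_single_gene(pile, loci = loci, f_init = th$f_init,
                                tolerance = th$tolerance,
                                error_rate = th$error_rate)
      write_pileups_tsv(pile, file.path(out, "snv",
                                        paste0(truth$sample_id, "_pileups.tsv")))
      write_variant_tsv(scr, file.path(out, "snv",
                                       paste0(truth$sample_id, ".tsv")),
                        sample_id = truth$sample_id)
      write_variant_vcf(scr, file.path(out, "snv",
                                       paste0(truth$sample_id, ".vcf")),
                        sample_id = truth$sample_id)
      scr
    }
    results$snv <- lapply(seq_len(nrow(cases)), function(i) {
      truth <- snv_case_truth(cases[i, ], loci = loci, seed = cseeds[i])
      run_one(truth, cases$depth[i], cseeds[i])
    })
    nctl <- cfg$cases$n_snv_controls
    if (nctl > 0) {
      ffs <- with_seed(seeds[5], stats::runif(nctl, 0.18, 0.25))
      results$snv_controls <- lapply(seq_len(nctl), function(i) {
        truth <- snv_control_truth(ffs[i], loci = loci,
                                   seed = cseeds[nrow(cases) + i],
                                   sample_id = sprintf("control%02d", i))
        run_one(truth, cfg$snv$mean_depth, cseeds[nrow(cases) + i])
      })
    }
  }

  manifest <- list(package = "nipt3",
                   version = as.character(utils::packageVersion("nipt3")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   thresholds = th,
                   panel_checksum = panel_checksum(panel),
                   n_background = length(cohort))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out, manifest = manifest, results = results))
}
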