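#' Bundled validation case configurations
#'
#' The package ships the case configurations of its clinical validation
#' cohort so simulation twins of the three screening arms can be generated:
#' seven aneuploid pregnancies (karyotype and fetal fraction per case),
#' three pregnancies carrying fetal duplications of at least 20 Mb, and
#' twelve pregnancies with fetal single-gene variants (mother/fetus genotype
#' per pathogenic locus, fetal fraction and mean hotspot depth per case).
#' Fetal fractions and depths are the measured per-case values; CNV
#' coordinates are the called spans placed at synthetic positions.
#'
#' @return A data.frame of case configurations (one row per case; the
#'   single-gene table carries a `loci` list-column of per-locus
#'   (locus_id, maternal, fetal) triples).
#' @export
demo_aneuploidy_cases <- function() {
  data.frame(
    sample_id = c("case51", "case52", "case53", "case54", "case55",
                  "case62", "case63"),
    karyotype = c("T13", "T18", "T18", "T21", "T21", "X0", "XXY"),
    chrom = c("13", "18", "18", "21", "21", NA, NA),
    sex_karyotype = c("XX", "XX", "XX", "XY", "XX", "X0", "XXY"),
    ff = c(0.1976, 0.1690, 0.1814, 0.1883, 0.2124, 0.1986, 0.1632),
    stringsAsFactors = FALSE)
}

#' @rdname demo_aneuploidy_cases
#' @export
demo_cnv_cases <- function() {
  df <- data.frame(
    sample_id = c("case59", "case58", "case58", "case60"),
    chrom = c("9", "12", "12", "20"),
    start = c(0, 0, 8e6, 0),
    end = c(21e6, 8e6, 31.5e6, 20e6),
    copy_delta = 1,
    ff = c(0.1699, 0.1796, 0.1796, 0.2022),
    sex_karyotype = c("XY", "XX", "XX", "XX"),
    stringsAsFactors = FALSE)
  df$size <- df$end - df$start
  df
}

#' @rdname demo_aneuploidy_cases
#' @export
demo_snv_cases <- function() {
  cfg <- list(
    list(id = "case117", ff = 0.2247, depth = 225,
         loci = list(c("PAH:c.G728A", "AB", "AB"))),
    list(id = "case118", ff = 0.2465, depth = 130,
         loci = list(c("PAH:c.A611G", "AB", "AB"))),
    list(id = "case108", ff = 0.2221, depth = 197,
         loci = list(c("GJB2:c.235delC", "AB", "AB"))),
    list(id = "case112", ff = 0.2522, depth = 271,
         loci = list(c("GJB2:c.G109A", "AB", "AB"))),
    list(id = "case109", ff = 0.2266, depth = 166,
         loci = list(c("GJB2:c.299_300del", "AA", "AB"),
                     c("GJB2:c.235delC", "AB", "AB"))),
    list(id = "case110", ff = 0.1966, depth = 155,
         loci = list(c("GJB2:c.299_300del", "AA", "AB"),
                     c("GJB2:c.235delC", "AB", "AB"))),
    list(id = "case111", ff = 0.1981, depth = 305,
         loci = list(c("SLC26A4:c.A1174T", "AB", "AB"))),
    list(id = "case239", ff = 0.2118, depth = 130,
         loci = list(c("HBB:c.126_129del", "AB", "AB"))),
    list(id = "case242", ff = 0.2135, depth = 201,
         loci = list(c("HBB:c.126_129del", "AB", "AB"),
                     c("HBB:c.316-197C>T", "AA", "AB"))),
    list(id = "case224a", ff = 0.2042, depth = 196,
         loci = list(c("HBB:c.126_129del", "AB", "AB"))),
    list(id = "case227", ff = 0.1810, depth = 181,
         loci = list(c("HBB:c.316-197C>T", "AB", "AB"),
                     c("HBB:c.126_129del", "AA", "AB"))),
    list(id = "case224b", ff = 0.2103, depth = 242,
         loci = list(c("HBB:c.A52T", "AB", "AB"))))
  df <- data.frame(
    sample_id = vapply(cfg, `[[`, character(1), "id"),
    ff = vapply(cfg, `[[`, numeric(1), "ff"),
    depth = vapply(cfg, `[[`, numeric(1), "depth"),
    stringsAsFactors = FALSE)
  df$loci <- lapply(cfg, `[[`, "loci")
  df
}

#' Build the sample truth of one aneuploidy case configuration
#'
#' @param case One row of [demo_aneuploidy_cases()].
#' @return A `sample_truth`.
#' @export
aneuploidy_case_truth <- function(case) {
  an <- if (!is.na(case$chrom))
    data.frame(chrom = case$chrom, state = "trisomy", stringsAsFactors = FALSE)
  sample_truth(case$ff, sex_karyotype = case$sex_karyotype,
               aneuploidies = an, sample_id = case$sample_id)
}

#' Build the sample truths of the CNV case configurations
#'
#' @param cases [demo_cnv_cases()] (or a subset).
#' @return Named list of `sample_truth`, one per sample.
#' @export
cnv_case_truths <- function(cases = demo_cnv_cases()) {
  lapply(split(cases, cases$sample_id), function(s) {
    sample_truth(s$ff[1], sex_karyotype = s$sex_karyotype[1],
                 cnvs = s[, c("chrom", "start", "end", "copy_delta")],
                 sample_id = s$sample_id[1])
  })
}

#' Build the sample truth of one single-gene case configuration
#'
#' Pathogenic loci are forced to the case's mother/fetus genotypes; all
#' other panel loci are drawn from Hardy-Weinberg + Mendelian transmission.
#'
#' @param case One row of [demo_snv_cases()] (with its `loci` entry).
#' @param loci Locus metadata ([default_locus_metadata()]).
#' @param seed Integer seed for the background genotypes.
#' @return A `sample_truth` with genotype maps over all loci.
#' @export
snv_case_truth <- function(case, loci = default_locus_metadata(), seed = 1) {
  force <- list()
  for (lc in case$loci[[1]]) force[[lc[1]]] <- lc[2:3]
  # variant-free at the other pathogenic loci: carrier mothers are possible
  # in the population draw but the fetus is forced variant-free there
  gt <- simulate_truth_genotypes(loci, seed = seed, force = force)
  path <- loci$locus_id[!is.na(loci$disease)]
  free <- setdiff(path, names(force))
  gt$maternal[free][gt$maternal[free] == "BB"] <- "AB"
  gt$fetal[free] <- ifelse(gt$maternal[free] == "BB", "AB", "AA")
  sample_truth(case$ff, maternal_genotypes = gt$maternal,
               fetal_genotypes = gt$fetal, sample_id = case$sample_id)
}

#' Build a variant-free single-gene sample truth
#'
#' A control pregnancy: no pathogenic fetal allele at any pathogenic locus
#' (the mother may still be a population carrier); common loci drawn from
#' Hardy-Weinberg.
#'
#' @param ff Fetal fraction.
#' @param loci Locus metadata.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A `sample_truth`.
#' @export
snv_control_truth <- function(ff, loci = default_locus_metadata(), seed = 1,
                              sample_id = "control") {
  gt <- simulate_truth_genotypes(loci, seed = seed)
  path <- loci$locus_id[!is.na(loci$disease)]
  gt$maternal[path][gt$maternal[path] == "BB"] <- "AB"
  gt$fetal[path] <- ifelse(gt$maternal[path] == "BB", "AB", "AA")
  sample_truth(ff, maternal_genotypes = gt$maternal,
               fetal_genotypes = gt$fetal, sample_id = sample_id)
}
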