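# Canonical order of the admissible pseudo-tetraploid combinations.
PTG_COMBOS <- c("AAAA", "AAAB", "ABAA", "ABAB", "ABBB", "BBAB", "BBBB")

#' The admissible pseudo-tetraploid genotype space
#'
#' A plasma sample is a mother+fetus mixture, so the genotype at a biallelic
#' locus is a 4-letter "pseudo-tetraploid": two maternal letters followed by
#' two fetal letters. Of the 9 maternal x fetal combinations, the two that
#' violate maternal transmission (AA x BB, BB x AA) cannot occur, leaving 7.
#' The space is derived by enumeration, not hard-coded.
#'
#' @return Character vector of the 7 admissible codes, canonical order.
#' @export
pseudo_tetraploid_space <- function() {
  grid <- expand.grid(maternal = GENOTYPES, fetal = GENOTYPES,
                      stringsAsFactors = FALSE)
  ok <- mendelian_ok(grid$maternal, grid$fetal)
  sort(paste0(grid$maternal[ok], grid$fetal[ok]))
}

maternal_part <- function(combo) substr(combo, 1, 2)
fetal_part <- function(combo) substr(combo, 3, 4)
b_count <- function(gt) vapply(strsplit(gt, ""), function(x) sum(x == "B"), 0L)

#' Expected mixture B-allele fraction of a combination
#'
#' p = (1 - f) * b_m / 2 + f * b_f / 2, where b_m and b_f are the B-allele
#' counts of the maternal and fetal genotypes. Constant in f for AAAA, ABAB
#' and BBBB; strictly monotone in f for the four informative combinations.
#'
#' @param combo A pseudo-tetraploid code (may be a vector).
#' @param f Fetal fraction in (0, 1).
#' @return Expected B-allele fraction(s) in \[0, 1\].
#' @export
expected_alt_fraction <- function(combo, f) {
  if (!(f > 0 && f < 1)) stop("fetal fraction must lie strictly in (0, 1)")
  if (!all(combo %in% PTG_COMBOS))
    stop("inadmissible pseudo-tetraploid combination: ",
         paste(setdiff(combo, PTG_COMBOS), collapse = ", "))
  (1 - f) * b_count(maternal_part(combo)) / 2 +
    f * b_count(fetal_part(combo)) / 2
}

#' Fetal-fraction-informative combinations
#'
#' The combinations whose expected mixture B-allele fraction depends on the
#' fetal fraction (maternal and fetal B-dose differ); only these carry
#' information for fetal-fraction estimation.
#'
#' @return Character vector (AAAB, ABAA, ABBB, BBAB).
#' @export
informative_combinations <- function() {
  space <- pseudo_tetraploid_space()
  dep <- abs(expected_alt_fraction(space, 0.1) -
             expected_alt_fraction(space, 0.4)) > 1e-12
  space[dep]
}

#' Binomial log-likelihood of a pileup under a combination
#'
#' log Binomial(alt_count | depth, p) with p the expected mixture B-allele
#' fraction clamped to \[error_rate, 1 - error_rate\]. Zero-depth pileups are
#' uninformative (log-likelihood 0 for every combination).
#'
#' @param pileup One pileup: list/row with ref_count and alt_count.
#' @param combo Pseudo-tetraploid code (vectorized).
#' @param f Fetal fraction.
#' @param error_rate Sequencing error floor in \[0, 0.5).
#' @return Log-likelihood(s).
#' @export
locus_log_likelihood <- function(pileup, combo, f, error_rate = 0.005) {
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must lie in [0, 0.5)")
  depth <- pileup$ref_count + pileup$alt_count
  if (depth == 0) return(rep(0, length(combo)))
  p <- pmin(pmax(expected_alt_fraction(combo, f), error_rate), 1 - error_rate)
  stats::dbinom(pileup$alt_count, size = depth, prob = p, log = TRUE)
}

# loci x combos log-likelihood matrix at fetal fraction f.
ptg_ll_matrix <- function(alt, depth, f, error_rate) {
  p <- pmin(pmax(expected_alt_fraction(PTG_COMBOS, f), error_rate),
            1 - error_rate)
  ll <- outer(seq_along(alt), seq_along(p), function(i, j)
    stats::dbinom(alt[i], size = depth[i], prob = p[j], log = TRUE))
  ll[depth == 0, ] <- 0
  colnames(ll) <- PTG_COMBOS
  ll
}

#' Hardy-Weinberg prior over the pseudo-tetraploid space
#'
#' Maternal genotype prior is Hardy-Weinberg at population B-allele frequency
#' q; the fetal prior is Mendelian transmission of one maternal allele plus a
#' paternal allele drawn at frequency q.
#'
#' @param q Population B-allele frequency (scalar or per-locus vector).
#' @return Matrix (length(q) x 7) of combination priors, rows summing to 1.
#' @export
hwe_prior <- function(q) {
  cbind(AAAA = (1 - q)^3, AAAB = q * (1 - q)^2, ABAA = q * (1 - q)^2,
        ABAB = q * (1 - q), ABBB = q^2 * (1 - q), BBAB = q^2 * (1 - q),
        BBBB = q^3)
}

resolve_prior <- function(prior, n) {
  if (is.null(prior))
    prior <- matrix(1 / 7, n, 7, dimnames = list(NULL, PTG_COMBOS))
  else if (is.vector(prior) && length(prior) == 7)
    prior <- matrix(prior, n, 7, byrow = TRUE, dimnames = list(NULL, PTG_COMBOS))
  else if (is.vector(prior) && length(prior) == n)
    prior <- hwe_prior(prior)
  prior <- as.matrix(prior)
  if (nrow(prior) != n || ncol(prior) != 7)
    stop("prior must be NULL, a 7-vector, a per-locus q vector, or an n x 7 matrix")
  prior / rowSums(prior)
}

#' EM estimation of the fetal fraction from allele pileups
#'
#' Alternates an E-step (posterior over the 7 combinations at the current
#' fetal fraction, given per-locus priors) with an M-step (1-D maximization
#' of the expected complete-data log-likelihood over f) until the change in
#' f falls below `tolerance`. The observed-data log-likelihood is
#' non-decreasing across iterations. If no locus carries fetal-fraction
#' information (posterior mass only on the f-constant combinations), the
#' estimate is flagged not converged.
#'
#' @param pileups data.frame with ref_count/alt_count (see
#'   [simulate_pileups()]).
#' @param prior NULL (uniform), a 7-vector over combinations, a per-locus
#'   population B-allele frequency vector, or an n x 7 matrix.
#' @param f_init Starting fetal fraction (default 0.10).
#' @param tolerance Convergence threshold on |f_t - f_(t-1)| (default 0.001).
#' @param max_iter Iteration cap.
#' @param error_rate Sequencing error floor.
#' @return An `ff_estimate`: list(f, n_iterations, trajectory, loglik,
#'   converged).
#' @export
estimate_fetal_fraction_em <- function(pileups, prior = NULL, f_init = 0.10,
                                       tolerance = 0.001, max_iter = 100,
                                       error_rate = 0.005) {
  stopifnot(nrow(pileups) >= 1, f_init > 0, f_init < 1)
  alt <- pileups$alt_count
  depth <- pileups$ref_count + pileups$alt_count
  pr <- resolve_prior(prior, length(alt))
  logpr <- log(pr)

  obs_ll <- function(f) {
    m <- ptg_ll_matrix(alt, depth, f, error_rate) + logpr
    mx <- apply(m, 1, max)
    sum(mx + log(rowSums(exp(m - mx))))
  }
  f <- f_init
  trajectory <- f
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- ptg_ll_matrix(alt, depth, f, error_rate) + logpr
    mx <- apply(m, 1, max)
    post <- exp(m - mx) / rowSums(exp(m - mx))
    loglik <- c(loglik, sum(mx + log(rowSums(exp(m - mx)))))

    q_fun <- function(ff) sum(post * ptg_ll_matrix(alt, depth, ff, error_rate))
    f_new <- stats::optimize(q_fun, interval = c(0.001, 0.499),
                             maximum = TRUE, tol = 1e-6)$maximum
    trajectory <- c(trajectory, f_new)
    if (abs(f_new - f) < tolerance) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  # the estimate is only credible if, at the fitted f, appreciable posterior
  # mass sits on informative combinations whose expected fraction is not
  # pinned at the error-rate clamp (otherwise the likelihood is locally flat
  # in f: e.g. only AAAA/ABAB/BBBB loci)
  m <- ptg_ll_matrix(alt, depth, f, error_rate) + logpr
  mx <- apply(m, 1, max)
  post <- exp(m - mx) / rowSums(exp(m - mx))
  p_f <- expected_alt_fraction(PTG_COMBOS, f)
  informative <- b_count(maternal_part(PTG_COMBOS)) !=
    b_count(fetal_part(PTG_COMBOS))
  usable <- informative & p_f > error_rate & p_f < 1 - error_rate
  if (converged && mean(rowSums(post[, usable, drop = FALSE])) < 1e-3) {
    converged <- FALSE
    warning("fetal-fraction estimate is unsupported: ",
            "no fetal-fraction-informative loci carry posterior mass")
  }
  structure(list(f = f, n_iterations = length(trajectory) - 1,
                 trajectory = trajectory, loglik = loglik,
                 converged = converged),
            class = "ff_estimate")
}

#' @export
print.ff_estimate <- function(x, ...) {
  cat(sprintf("<ff_estimate> f = %.4f (%d EM iterations, %sconverged)\n",
              x$f, x$n_iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' MAP pseudo-tetraploid genotype per locus
#'
#' posterior(combo) proportional to prior(combo) x likelihood at the given
#' fetal fraction; the MAP combination breaks ties toward the earlier
#' canonical code. The reported PGC string uses the field's casing: maternal
#' letters uppercase, fetal lowercase ("ABab").
#'
#' @inheritParams estimate_fetal_fraction_em
#' @param f Fetal fraction (typically the EM estimate).
#' @return data.frame(locus_id, map_combo, pgc, fetal_call, posterior) plus
#'   the full posterior matrix as attribute "posterior".
#' @export
map_genotypes <- function(pileups, f, prior = NULL, error_rate = 0.005) {
  stopifnot(f > 0, f < 1)
  alt <- pileups$alt_count
  depth <- pileups$ref_count + pileups$alt_count
  pr <- resolve_prior(prior, length(alt))
  m <- ptg_ll_matrix(alt, depth, f, error_rate) + log(pr)
  mx <- apply(m, 1, max)
  post <- exp(m - mx) / rowSums(exp(m - mx))
  map <- PTG_COMBOS[apply(post, 1, which.max)]
  out <- data.frame(locus_id = pileups$locus_id %||% seq_along(alt),
                    map_combo = map,
                    pgc = paste0(maternal_part(map), tolower(fetal_part(map))),
                    fetal_call = fetal_part(map),
                    posterior = post[cbind(seq_along(map), match(map, PTG_COMBOS))],
                    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  out
}

#' Bundled hotspot locus metadata
#'
#' The nine pathogenic hotspot loci screened in the package's demonstration
#' configurations (all autosomal recessive), with gene, disease label,
#' inheritance and population B-allele frequency. Optionally appends
#' `n_common` synthetic common SNP loci (population frequency `common_freq`)
#' representing the rest of the hotspot windows; these power fetal-fraction
#' estimation but are not pathogenic.
#'
#' @param n_common Number of common (non-pathogenic) loci to append.
#' @param common_freq Population B-allele frequency of the common loci.
#' @return data.frame(locus_id, gene, disease, inheritance, pop_b_freq).
#' @export
default_locus_metadata <- function(n_common = 200, common_freq = 0.30) {
  path <- data.frame(
    locus_id = c("PAH:c.G728A", "PAH:c.A611G",
                 "GJB2:c.235delC", "GJB2:c.G109A", "GJB2:c.299_300del",
                 "SLC26A4:c.A1174T",
                 "HBB:c.126_129del", "HBB:c.316-197C>T", "HBB:c.A52T"),
    gene = c("PAH", "PAH", "GJB2", "GJB2", "GJB2", "SLC26A4",
             "HBB", "HBB", "HBB"),
    disease = c("phenylketonuria", "phenylketonuria", "hearing-loss",
                "hearing-loss", "hearing-loss", "hearing-loss",
                "beta-thalassemia", "beta-thalassemia", "beta-thalassemia"),
    inheritance = "AR", pop_b_freq = 0.01, stringsAsFactors = FALSE)
  if (n_common > 0) {
    common <- data.frame(
      locus_id = sprintf("SNP%04d", seq_len(n_common)),
      gene = NA_character_, disease = NA_character_,
      inheritance = NA_character_, pop_b_freq = common_freq,
      stringsAsFactors = FALSE)
    path <- rbind(path, common)
  }
  path
}

#' Call fetal variants and disease status from locus genotypes
#'
#' Per pathogenic locus: fetal BB is reported homozygous, AB heterozygous
#' (one pathogenic allele), AA is "ND". Per gene (all panel diseases are
#' autosomal recessive): two pathogenic alleles across the gene's loci
#' (homozygous or compound heterozygous) give "affected", one "carrier",
#' zero "non-carrier".
#'
#' @param calls A [map_genotypes()] table.
#' @param loci Locus metadata (see [default_locus_metadata()]); every
#'   pathogenic call must have metadata.
#' @return list(loci, genes) of class `variant_calls`: locus-level reported
#'   variants and gene-level disease status.
#' @export
call_variants <- function(calls, loci = default_locus_metadata()) {
  unknown <- setdiff(calls$locus_id, loci$locus_id)
  if (length(unknown))
    stop("no locus metadata for: ", paste(utils::head(unknown, 3), collapse = ", "))
  meta <- loci[match(calls$locus_id, loci$locus_id), ]
  path <- !is.na(meta$disease)
  lv <- data.frame(locus_id = calls$locus_id[path],
                   gene = meta$gene[path], disease = meta$disease[path],
                   pgc = calls$pgc[path],
                   map_combo = calls$map_combo[path],
                   fetal_call = calls$fetal_call[path],
                   reported = c(AA = "ND", AB = "heterozygous",
                                BB = "homozygous")[calls$fetal_call[path]],
                   stringsAsFactors = FALSE)
  rownames(lv) <- NULL
  genes <- do.call(rbind, lapply(split(lv, lv$gene), function(g) {
    n_alleles <- sum(c(AA = 0, AB = 1, BB = 2)[g$fetal_call])
    data.frame(gene = g$gene[1], disease = g$disease[1], n_alleles = n_alleles,
               status = if (n_alleles >= 2) "affected"
                        else if (n_alleles == 1) "carrier" else "non-carrier",
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(loci = lv, genes = genes), class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  hit <- x$loci[x$loci$reported != "ND", , drop = FALSE]
  cat(sprintf("<variant_calls> %d fetal variant(s) reported at %d pathogenic loci\n",
              nrow(hit), nrow(x$loci)))
  if (nrow(hit)) print(hit[, c("locus_id", "pgc", "reported")])
  aff <- x$genes[x$genes$status != "non-carrier", , drop = FALSE]
  if (nrow(aff)) print(aff)
  invisible(x)
}

#' Single-gene disorder screen of one sample
#'
#' EM fetal-fraction estimation over all loci, MAP genotyping at the
#' estimate, and variant/disease calling at the pathogenic loci.
#'
#' @param pileups data.frame(locus_id, ref_count, alt_count).
#' @param loci Locus metadata; priors are Hardy-Weinberg at each locus's
#'   population B-allele frequency.
#' @inheritParams estimate_fetal_fraction_em
#' @return list(ff, genotypes, variants) of class `ptg_screen`.
#' @export
screen_single_gene <- function(pileups, loci = default_locus_metadata(),
                               f_init = 0.10, tolerance = 0.001,
                               max_iter = 100, error_rate = 0.005) {
  meta <- loci[match(pileups$locus_id, loci$locus_id), ]
  if (any(is.na(meta$pop_b_freq)))
    stop("missing locus metadata for some pileup loci")
  prior <- hwe_prior(meta$pop_b_freq)
  ff <- estimate_fetal_fraction_em(pileups, prior = prior, f_init = f_init,
                                   tolerance = tolerance, max_iter = max_iter,
                                   error_rate = error_rate)
  genotypes <- map_genotypes(pileups, f = ff$f, prior = prior,
                             error_rate = error_rate)
  variants <- call_variants(genotypes, loci = loci)
  structure(list(ff = ff, genotypes = genotypes, variants = variants),
            class = "ptg_screen")
}

#' @export
print.ptg_screen <- function(x, ...) {
  print(x$ff); print(x$variants)
  invisible(x)
}

#' Write pileups / variant calls
#'
#' `write_pileups_tsv` writes the locus_id/ref/alt/ref_count/alt_count table;
#' `write_variant_tsv` mirrors the clinical report layout (sample, gene,
#' variant, PGC, status); `write_variant_vcf` writes a minimal VCF with one
#' record per reported fetal variant.
#'
#' @param pileups,screen,path Data and output path; `sample_id` labels the
#'   report rows.
#' @return `path`, invisibly.
#' @export
write_pileups_tsv <- function(pileups, path) write_tsv(pileups, path)

#' @rdname write_pileups_tsv
#' @export
read_pileups_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("locus_id", "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname write_pileups_tsv
#' @export
write_variant_tsv <- function(screen, path, sample_id = "sample") {
  lv <- screen$variants$loci
  df <- data.frame(sample = sample_id, gene = lv$gene, variant = lv$locus_id,
                   pgc = lv$pgc, mutation = ifelse(lv$reported == "ND", "ND",
                                                   lv$locus_id),
                   status = lv$reported,
                   fetal_fraction = round(screen$ff$f, 4),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_pileups_tsv
#' @export
write_variant_vcf <- function(screen, path, sample_id = "sample") {
  lv <- screen$variants$loci
  hit <- lv[lv$reported != "ND", , drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              "##source=nipt3",
              paste0("##SAMPLE=<ID=", sample_id, ">"),
              "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
              "##INFO=<ID=FGT,Number=1,Type=String,Description=\"Fetal genotype call\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(hit)) sprintf(".\t0\t%s\tA\tB\t.\tPASS\tGENE=%s;FGT=%s",
                                 hit$locus_id, hit$gene, hit$fetal_call)
          else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}
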