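---
title: "Models and design of the nipt3 three-arm screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the nipt3 three-arm screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cell-free DNA (cfDNA) in a pregnant woman's plasma is a mixture of maternal
and placental (fetal) fragments; the fetal fraction *f* is typically 4-25%.
A single targeted-capture sequencing run of that mixture can, in principle,
screen three very different classes of fetal disorder at once:

1. **whole-chromosome aneuploidy** (trisomy 13/18/21, 45,X, 47,XXY) from
   chromosome-level read-depth shifts,
2. **sub-chromosomal copy-number variants** (CNVs) from region-level depth
   shifts, and
3. **single-gene (monogenic) disorders** from allele fractions at known
   pathogenic hotspot loci.

`nipt3` implements the full bioinformatics side of such a 3-in-1 screen,
starting from per-region unique-read counts and per-locus allele pileups
(alignment and sequencing-level QC are upstream and out of scope), together
with a cohort simulator so every arm can be exercised and validated end to
end on synthetic data.

# The target panel

The capture design the pipeline assumes has two kinds of regions:

* **backbone regions** — 8,171 equal-length (~100 bp) regions spread across
  all chromosomes: 7,631 on the 22 autosomes, 452 on X and 88 on Y. Only
  these feed the count-based statistics. The design holds GC content
  constant across regions, which is why the pipeline carries no GC
  correction stage: the panel is assumed to have engineered the bias away.
* **hotspot regions** — 560 variable-length windows tiling mutation hotspots
  of six autosomal-recessive disease genes (hearing impairment: *GJB2*,
  *GJB3*, *SLC26A4*; β-thalassemia: *HBB*; phenylketonuria /
  hyperphenylalaninemia: *PAH*, *PTS*). These provide the allele pileups for
  the single-gene arm and play no role in the count statistics.

The real panel's coordinates are proprietary, so `generate_panel_layout()`
produces a statistically equivalent synthetic layout: backbone counts are
apportioned to chromosomes by largest-remainder on chromosome length
(with X and Y pinned to 452 and 88 to match the published region counts,
which deviate from proportionality), regions are evenly spaced within each
chromosome, and hotspot windows are appended at synthetic gene loci.
Coordinates are 0-based half-open everywhere, matching BED.

# The cohort simulator

The simulator is the package's definition of the study conditions, not a
tuning knob.

**Counts.** A sample's backbone counts are multinomial with expected
proportions ∝ (uniform capture weight) × (copy dose). The dose model is the
two-genome mixture: a fetal single-copy gain multiplies a region's dose by
(1 + *f*/2), a loss by (1 − *f*/2); chrY carries *f*/2 of an autosomal dose
for a male fetus and exactly 0 for a female fetus; 45,X has X dose
1 − *f*/2; 47,XXY has X dose 1.0 (the fetus contributes two X copies, like
its mother) plus the male Y dose — which is why an XXY pregnancy shows a
near-zero X Z-value but a clear Y signal. With `dispersion` > 0 the region
weights are first perturbed by independent Gamma noise with unit mean and
variance `dispersion` (a Dirichlet-multinomial with per-region concentration
1/`dispersion`), modelling residual capture variability between libraries.

The default `dispersion = 2.5e-4` (region-level CV ≈ 1.6%) was chosen once,
to make the simulated assay's region-level noise match what the assay's own
reported case statistics imply: the published CNV cases show median region
Z-values of ≈2.6-5.3 at dose shifts of *f*/2 ≈ 0.085-0.10, which requires a
total background region CV of ~2-3%. At 10 million reads per sample the
simulated CNV cases land in exactly that median-Z range. A larger dispersion
(e.g. 2e-3) would make the |median Z| > 2 calling criterion unattainable at
any depth for fetal fractions below ~20%, contradicting the assay's
observed behaviour. Chromosome-level Z-values are insensitive to this
choice because they are standardized by the background cohort's own SD.

Default read depths are 2 million unique reads per sample for the
aneuploidy arm and 10 million for the CNV arm; hotspot locus depth is
Poisson around the recorded per-case mean (130-305×, default 200×).
Background fetal fractions are drawn uniformly from 16-25%, matching the
range of the validation pregnancies. Maternal CNVs, GC bias, mappability
and read-level artefacts are deliberately not simulated — passing tests
show the statistical machinery is correct under the stated noise model,
not that the pipeline is robust to biases the panel design is assumed to
remove.

**Pileups.** At each hotspot locus the alt-read count is Binomial(depth,
*p*) with *p* the expected mixture B-allele fraction of the mother-fetus
genotype pair (below), clamped to [`error_rate`, 1 − `error_rate`]
(default 0.005) to absorb sequencing error at homozygous sites.

# Arm 1: chromosome aneuploidy by Z-value

Counts are standardized to one million reads — over the 7,631 autosomal
regions for autosomal statistics and over all 8,171 backbone regions for
X/Y. The chromosome statistic is the mean normalized depth of the
chromosome's regions; a 68-sample euploid background supplies its mean and
(n−1) SD, and

  Z_c = (statistic_c − mean_c) / sd_c.

Trisomy is called at Z ≥ 3, monosomy at Z ≤ −3. The threshold is the NIPT
convention; the assay's own positive calls all sit at |Z| ≥ 3.6, so 3 is
conservative on the detection side. Fetal sex uses the median and mean
depth over the 88 chrY regions: male when both exceed 25% of the mean
male-pregnancy Y dose estimated from the XY background stratum (robust to
fetal fractions down to ~1/4 of the background mean). Sex-karyotype
refinement uses the X Z-value against the XX-fetus stratum: Y signal with
the expected male X deficit → XY; Y signal with XX-level X dose → XXY; no Y
signal with X deficit → 45,X; conflicting signals → "other", flagged for
review.

Two stratification decisions are the package's own: the X and Y baselines
(chromosome- and region-level) are computed per fetal-sex stratum of the
background, because a mixed-sex background makes X/Y variances bimodal; and
the published sex-chromosome quality filter (a base-quality subset of 25
samples) cannot be reproduced at count level, so the Y baseline defaults to
all background samples.

**A known, quantified limitation.** With 22 autosomes tested at |Z| ≥ 3,
the probability that an euploid sample shows *some* autosomal excursion is
at least 1 − 0.9973²² ≈ 5.8% even for perfectly normal Z, and ≈7-9% when
the baseline mean/SD are estimated from 68 samples. The pipeline's
simulated per-sample false-positive rate (~9% over 200 euploid samples) is
therefore a property of the decision rule itself, not of the
implementation; a production deployment would either confirm positives on
a second statistic or raise the cut. Detection of the validation
karyotypes is unaffected (case Z-values are 12-16 at the recorded fetal
fractions).

# Arm 2: CNVs by HaarSeg segmentation of region Z

Region-level Z-values use the same standardization with per-region
background means and SDs (isolated zero SDs are floored to the smallest
positive SD; a fully degenerate background is refused at scoring time).
Each chromosome's Z profile is segmented with a Haar-wavelet scheme:

1. convolve with Haar step wavelets at dyadic scales 2⁰..2⁴
   (`max_scale = 5`);
2. take local maxima of the absolute convolution as breakpoint candidates;
3. keep candidates by Benjamini-Hochberg FDR at `fdr_q = 0.001`, against a
   robust noise estimate σ = MAD(lag-1 differences)/√2;
4. unify across scales, finer scales taking precedence (a coarser candidate
   is added only if no accepted breakpoint lies within half its support);
5. refine each accepted breakpoint to the least-squares split position
   within its half-support window (coarse-scale peaks alone are localized
   only to ~half the wavelet support).

The result is a deterministic partition; tests verify exact recovery of
noiseless steps and near-optimality (≤110% of the exhaustive
dynamic-programming optimum) on noisy profiles.

A segment becomes a CNV call only if **all** of: (1) ≥20 consecutive
regions **and** a genomic span ≥10 Mb; (2) mean Z outside [−0.7, 0.7];
(3) median Z outside [−2, 2]; (4) median Z outside the 95% interval of
background segment medians. Criterion (1) is stated ambiguously in the
assay's description ("at least 20 continuous regions have the resolution
larger than 10 Mb"); the conjunction is adopted because it is the
conservative reading and reproduces the assay's inability to call <2 Mb
events. Criterion (4)'s background interval is computed by running the same
segmentation over every background sample and pooling segment medians
(2.5th-97.5th percentiles); a simpler variant using per-sample whole-median
values is available via `background_interval = "sample"`. X/Y segments are
scored but suppressed from the call set when the sex karyotype is abnormal,
so a 45,X is not double-reported as an X deletion.

At the validation conditions (duplications ≥20 Mb, *f* = 0.17-0.20, 10M
reads) detection is complete and boundaries agree with truth to within one
inter-region spacing in ~95% of events per boundary; the residual
off-by-two cases are least-squares-optimal given the noise (an exhaustive
segmenter picks the same split), i.e. a resolution limit of the data.
Adjacent same-direction events merge into one segment — they are
dose-indistinguishable — and are judged against their union.

# Arm 3: single-gene disorders by pseudo-tetraploid genotyping

At a biallelic locus the plasma sample is treated as a four-allele
"pseudo-tetraploid": two maternal letters then two fetal letters over
{A = reference base, B = most frequent non-reference base, fixed per locus
in the panel metadata}. Enumerating the 3×3 mother×fetus genotype pairs and
removing the two that violate maternal transmission (AA×BB, BB×AA) leaves
seven admissible combinations {AAAA, AAAB, ABAA, ABAB, ABBB, BBAB, BBBB}.
The expected mixture B-allele fraction is

  p(combo, f) = (1 − f)·b_m/2 + f·b_f/2,

with b_m, b_f the maternal/fetal B-allele counts. Four combinations (AAAB,
ABAA, ABBB, BBAB) have b_m ≠ b_f and are the only ones informative for the
fetal fraction.

The published description names an EM algorithm for the fetal fraction and
a Bayesian model for genotypes without printing the count likelihood; this
implementation concretizes both with the standard cfDNA binomial model:
log L(locus | combo, f) = log Binomial(alt | depth, clamp(p(combo, f))).
The EM alternates a posterior over the seven combinations per locus
(E-step; priors below) with a 1-D maximization of the expected
complete-data log-likelihood over f ∈ (0.001, 0.499) via `optimize()`
(M-step), from `f_init = 0.10`, stopping when successive estimates differ
by less than 0.001 (the assay's stated tolerance; `max_iter = 100`). The
observed-data log-likelihood is non-decreasing by the usual EM argument and
is asserted per iteration in the tests. If, at the fitted f, essentially no
posterior mass lies on informative combinations away from the error-rate
clamp, the likelihood is locally flat in f and the estimate is flagged
`converged = FALSE` — this is what happens when only AAAA/ABAB/BBBB loci
are present.

The default prior is Hardy-Weinberg at each locus's population B-allele
frequency (0.01 for pathogenic hotspots, 0.30 for the common SNPs that
power fetal-fraction estimation), with the fetal allele given by Mendelian
transmission plus a population-frequency paternal allele; a uniform prior
is available. MAP genotyping at the EM estimate breaks ties toward the
earlier canonical code, for determinism. Per pathogenic locus, fetal AB is
reported as a heterozygous (carrier) allele and BB as homozygous; per gene,
two pathogenic alleles across its loci (homozygous or compound
heterozygous, all six genes being autosomal recessive) give "affected",
one "carrier", zero "non-carrier". Indels are treated as biallelic ref/alt
counts; realignment subtleties live upstream of the pileup abstraction.

The hard confusions are exactly the ones the assay itself reports: at
f ≈ 0.20 and depth 200 the expected fractions of ABAA/ABAB/ABBB are
0.40/0.50/0.60, about 1.5 binomial SEs apart, so ABab↔ABaa swaps occur in
roughly 10% of loci and dominate the misses; homozygous-like classes are
called essentially perfectly. Sensitivity is monotone in both f and depth
(tested on a grid).

# Validation experiments and problem sizes

`twin_aneuploidy()`, `twin_cnv()` and `twin_snv()` re-create the assay's
three evaluation cohorts on synthetic data: the seven aneuploid cases
(T13, T18×2, T21×2, 45,X, 47,XXY at their recorded fetal fractions) against
a 68-sample background at 2M reads; the three ≥20 Mb duplications (21 Mb,
8+23.5 Mb adjacent, 20 Mb at f = 16.99-20.22%) at 10M reads; and the twelve
variant-carrying pregnancies (recorded genotype configurations, fetal
fractions and depths) plus ten variant-free controls. Rates are Monte-Carlo
estimates over 3-5 replicate case cohorts. `scripts/acceptance.R` runs all
of them from scratch and writes the headline numbers as JSON; the test
suite asserts the same experiments at fixed seeds. Test problem sizes
(a 40×-scaled 800-region panel for unit tests, full 8,731-region panel for
the validation experiments) are the package's chosen balance between
statistical resolution and turnaround.

# Known limitations

* The per-sample euploid false-positive rate of the |Z| ≥ 3 rule over 22
  autosomes is ≥5.8% by construction (see Arm 1); interpret isolated
  borderline excursions accordingly.
* CNV boundaries are resolved to the inter-region spacing (~380 kb) at
  best, and events below ~2 Mb (fewer than 20 regions) are structurally
  uncallable under the stated criteria — by design, mirroring the assay.
* The simulator's clean chrY dose (exactly zero for female fetuses) cannot
  reproduce the degenerate female Y baselines real data sometimes show
  (e.g. a constant Y Z for all female samples); Y-based sex calls on real
  data need the configurable male threshold revisited against that lab's
  background.
* Fetal-fraction estimates inherit a small upward bias (~0.005) from the
  clamp at homozygous loci; it is immaterial at validation depths but
  visible in the recovery tests' tolerance (±0.02).
* The single-gene arm assumes the mother's genotype is recoverable from the
  same pileup; severely skewed maternal coverage or maternal CNVs over a
  hotspot would violate the mixture model.
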