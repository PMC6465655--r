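Package: nipt3
Title: Three-in-One Noninvasive Prenatal Testing from Targeted cfDNA Counts and Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated noninvasive prenatal testing (NIPT) pipeline for
    targeted-capture cell-free DNA data. Calls whole-chromosome aneuploidies by
    Z-value against a euploid background cohort, detects sub-chromosomal copy
    number variants by Haar-wavelet (HaarSeg) segmentation of region-level
    Z-values with conservative size and magnitude criteria, and screens
    single-gene disorders with a pseudo-tetraploid mother-fetus genotype model
    (EM fetal-fraction estimation and Bayesian MAP genotyping). Includes a
    cohort simulator for backbone region read counts and hotspot allele
    pileups so the whole pipeline can be exercised end to end on synthetic
    maternal-fetal mixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
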