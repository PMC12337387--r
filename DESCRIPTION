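Package: layscan
Title: Laying-Curve Traits, Haplotype-Block Association and Polygenic
    Selection Scans for Egg Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetics of egg-production
    efficiency from daily laying records and phased genotypes. Fits
    laying-rate curves (Wood, compartmental, Yang-Ning), locates the
    stationary point and splits the cycle into up- and sustained
    stages; derives production, clutch and interval traits from daily
    binary records; runs single-SNP mixed-linear-model scans,
    haplotype-block scans with a Ferdosi-style haplotype relationship
    matrix, and multi-trait canonical-correlation scans; predicts
    phenotypes from significant haplotype alleles (HPPS, HBLUP) and
    genomic BLUP under a fixed-validation-set cross-validation
    protocol; estimates variance explained by significant versus
    insignificant loci with two-component EM-REML; computes
    singleton-density selection scores, trait-polarized tSDS trend
    tests, and windowed Tajima's D and nucleotide diversity; and
    scores the enrichment of beneficial haplotype alleles across
    population panels. A seed-reproducible simulator supplies phased
    haplotypes with linkage disequilibrium, planted quantitative trait
    loci and Bernoulli daily laying records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    emmeans,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
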