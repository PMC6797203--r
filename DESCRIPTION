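Package: GSfix
Title: Genomic Selection with Large-Effect SNPs as Fixed Effects and
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genomic selection in a
    maize backcross-derived (BC1F3:4) biparental population. Simulates the
    breeding scheme (backcross to the recurrent parent, bulk-pollen
    intermating, selfing) on a multi-chromosome genetic map, generates
    multi-environment phenotypes with known architecture, fits
    multi-environment mixed models for BLUEs and entry-mean heritability,
    performs mixed-model GWAS with a VanRaden genomic relationship matrix,
    decomposes phenotypic variance over top-ranked SNPs by sequential
    regression, and runs GBLUP and Bayesian multi-kernel genomic prediction
    (single-environment, across-environment and genotype-by-environment
    models) under repeated five-fold, CV1 and CV2 cross-validation, with
    optional large-effect SNPs fitted as fixed effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
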