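Package: carpgs
Title: Genomic Evaluation of Juvenile Growth in Common Carp
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for genomic evaluation of
    juvenile growth traits in common carp (Cyprinus carpio) bred by
    partial factorial mating. Generates synthetic populations with a
    fixed 50-linkage-group genome, performs SNP quality control,
    Mendelian-exclusion parentage assignment, pedigree (A) and VanRaden
    genomic (G) relationship matrices, AI-REML variance-component and
    heritability estimation under the animal model (univariate and
    bivariate), two-step mixed-model association scans, and repeated
    fivefold cross-validation of PBLUP and GBLUP breeding-value
    prediction accuracy across marker-density scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
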