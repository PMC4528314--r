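Package: crossblup
Title: Genomic Prediction Across Purebred and Crossbred Pig Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic prediction (GBLUP) and pedigree-based prediction
    (PED-BLUP) in multi-line pig breeding programs, where selection acts on
    purebred nucleus lines but the commercial product is a crossbred animal.
    Implements deregression of estimated breeding values with heterogeneous
    reliability weights, pedigree (A) and genomic (G) relationship matrices
    including an across-population G centered with line-specific allele
    frequencies, REML estimation of variance components, heritabilities and
    purebred-crossbred genetic correlations, and a replicated cross-validation
    scenario engine reporting prediction accuracy and dispersion bias for
    within-, multi-, across-population and purebred-to-crossbred designs. A
    synthetic-population module simulates two diverged purebred lines plus an
    F1 cross so the entire pipeline can be exercised and validated without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
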