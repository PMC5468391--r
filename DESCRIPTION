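Package: AquaBLUP
Title: Animal-Model BLUP, REML and Genotype-by-Environment Analysis for
    Aquaculture Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-based quantitative genetics for fish breeding
    programs: numerator relationship matrices and their sparse inverses
    with inbreeding, Henderson's mixed-model equations for BLUE/BLUP,
    restricted maximum likelihood estimation of additive, common full-sib
    and residual variance components (univariate and bivariate, including
    cross-environment genetic correlations for genotype-by-environment
    assessment), logit sire-model heritability for binary survival with
    observed/liability scale transformations, genetic-trend computation
    from estimated breeding values, and a breeding-program simulator with
    truncation selection under per-family caps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
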