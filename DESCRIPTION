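Package: rejuvenomics
Title: Multi-Omic Detection of Partial Rejuvenation After Transient Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting epigenetic, transcriptomic and
    longitudinal rejuvenation in three-group (young / old / old-treated)
    designs, as arise in transient OSKM reprogramming studies. Implements
    region-level RRBS differential methylation (promoter/enhancer definition,
    coverage filtering, binomial-regression testing with a percentage-point
    effect rule), nearest-mean rejuvenation and temporal classification,
    expression preprocessing (quantile normalization, covariate removal),
    aging-DEG selection, gene-set signature scoring with global-signature
    correction, competitive rotation gene-set testing with the re-standardized
    maxmean statistic, a Normal-Normal hierarchical pattern model with
    Bayesian FDR selection and sample-randomization control, and paired /
    mixed-model longitudinal analyses. Ships seeded synthetic-data generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    Matrix,
    lme4,
    lmerTest,
    limma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    broom
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
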