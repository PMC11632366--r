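Package: CVRseek
Title: Data-Driven Discovery of Composite-Value-Ratio PET Biomarkers for
    Longitudinal Clinical Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers ratio-based longitudinal biomarkers (composite value
    ratios, CVR) from regional PET standardized-uptake-value and volume
    tables. A constrained genetic algorithm searches over numerator and
    denominator region sets; candidates are scored by a fitness combining
    per-arm clinical-trial sample-size estimates, derived from a linear
    mixed-effects model with correlated random intercepts and slopes on the
    log biomarker, with cognitive-group trajectory separation. Includes the
    literature-inspired SUVR baseline grid, regional ablation, parametric
    bootstrap confidence intervals, Gaussian-mixture amyloid-positivity
    screening, and a synthetic longitudinal cohort generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    mclust,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, BiomedicalInformatics
RoxygenNote: 7.3.3
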