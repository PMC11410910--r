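Package: uratephewas
Title: Phenome-Wide Association, Disease Trajectory and Factorial
    Mendelian Randomization Analysis of Serum Urate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying the health consequences of
    serum uric acid in biobank-scale cohorts. Implements phecode-based
    phenome construction with control exclusion ranges and an incident-case
    washout, observational and polygenic-risk-score phenome-wide association
    scans with Benjamini-Hochberg control, sex- and kidney-function-stratified
    scans with heterogeneity tests, restricted-cubic-spline non-linearity
    follow-up, a three-step disease-trajectory network builder (binomial
    direction tests plus matched conditional logistic regression, with death
    as a terminal node), drug-target genetic score construction by regional
    LD clumping, and a two-by-two factorial Mendelian randomization design
    for combination-therapy effects. A synthetic-cohort generator emulating
    the statistical structure of the real data makes every stage testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
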