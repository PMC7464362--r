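Package: mimnet
Title: Meet-in-the-Middle Screening of Early-Life BMI Milestones, Metabolite
    Networks, and Adolescent Metabolic Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking early-life body mass index (BMI) trajectory
    milestones (the infancy BMI peak and the childhood BMI rebound) to
    adolescent metabolic risk through consensus metabolite co-abundance
    networks. Provides a synthetic-cohort generator with known ground truth;
    natural-cubic-spline mixed models for estimating per-child milestone age
    and magnitude; metabolomics preprocessing (endogenous filter,
    half-minimum imputation, log10 transform, Pareto scaling); sex-stratified
    consensus weighted correlation networks (signed Spearman adjacency,
    topological overlap, dynamic tree cut, module eigengenes, kME
    membership); an externally standardized metabolic syndrome z-score; and
    the sex-stratified three-step meet-in-the-middle association screen with
    Benjamini-Hochberg false discovery rate control, tiered covariate
    models, component follow-up, and mutual-adjustment sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
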