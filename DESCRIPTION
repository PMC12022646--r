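Package: lipidcohort
Title: Quantification, QC-Anchored Batch Correction and Variability
    Analysis for Targeted Clinical Lipidomics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the statistical workflow of large targeted
    (SRM) lipidomics cohort studies: quantification of lipid
    concentrations from peak areas by stable isotope dilution,
    correction of type-II isotopic overlap between coeluting
    same-class species, between-batch drift correction anchored on
    periodic reference-plasma quality-control injections, CV-based
    retention filtering, decomposition of analytical, within-subject
    and between-subject variability (including intraclass correlation
    from mixed models), distance-based individuality analysis, and
    per-lipid sex-difference estimation with linear mixed models and
    false-discovery-rate control. Includes a synthetic cohort
    generator emulating a multi-batch, repeated-measures population
    study design so that every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    lme4,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
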