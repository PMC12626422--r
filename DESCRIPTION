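Package: dyadsync
Title: Dyadic Naturalistic fMRI Analysis of Social Brain Maturity and Synchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for naturalistic movie-viewing fMRI in
    child-mother dyads. Provides a Theory-of-Mind / Social-Pain-Matrix
    region-of-interest atlas with spherical timecourse extraction,
    timecourse-level signal conditioning (detrending, confound regression,
    band-pass filtering, framewise-displacement scrubbing), reverse-correlation
    event detection on group network timecourses, inter-region correlation
    matrices with a child-to-adult neural maturity score, child-mother versus
    child-stranger inter-subject synchronization (whole-run and
    event-restricted), the accompanying inferential layer (correlations,
    partial correlations, FDR, t tests, two-way ANOVA), and a synthetic
    dyadic-BOLD generator with planted event, age, and relationship-quality
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    RNifti,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
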