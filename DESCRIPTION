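Package: langmarker
Title: Smartphone Language Markers of Posttraumatic Symptom Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and internally validating smartphone-keyboard
    language markers of posttraumatic symptom severity. Daily word bags are
    scored against category and weighted lexicons, planned-missing flash-survey
    items are reduced to per-domain factor scores by a pooled one-factor
    confirmatory measurement model fitted by full-information maximum
    likelihood, and each (feature, domain) pair is analysed with a bivariate
    linear mixed model that decomposes the association into a between-subject
    (cross-sectional) and a within-subject (longitudinal) correlation.
    Candidate markers are screened on a random half of participants with a
    false-discovery-rate correction and confirmed on the other half with a
    Bonferroni correction; validated longitudinal markers are evaluated as
    sign-of-change predictors of symptom worsening. A synthetic cohort
    generator with known planted correlation structure makes every stage
    testable without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
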