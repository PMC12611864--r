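Package: aefisignal
Title: Disproportionality Signal Detection for Infant Combination-Vaccine
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative safety-signal analysis of spontaneous
    adverse-event reports following pentavalent (DTaP-IPV-Hib) and hexavalent
    (DTaP-IPV-Hib-HepB) infant vaccination. Reads the VAERS public-extract CSV
    dialect, builds an analysis-ready cohort (vaccine-name classification, age
    window, de-duplication, exclusion of error-only reports), computes four
    disproportionality statistics per adverse event -- reporting odds ratio,
    proportional reporting ratio, the BCPNN information component with its
    lower credible bound, and the empirical-Bayes gamma-Poisson shrinker --
    applies published signal thresholds with a two-of-four consensus rule,
    runs age/sex/severity-stratified analyses, and fits a multivariable
    logistic model of death classification. A seeded synthetic-report
    generator with planted signals and a deterministic summary fixture make
    every stage testable without the external extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
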