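Package: faersignal
Title: Disproportionality Signal Detection and Prioritization for FAERS
    Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) quarterly extract bundles: parsing of
    the $-delimited ASCII tables, case-level deduplication, target-drug
    cohort construction with MedDRA PT-to-SOC mapping, reporting odds
    ratio (ROR) disproportionality screening with stratification,
    serious versus non-serious comparisons (Pearson chi-squared, Fisher
    exact, Mann-Whitney), a five-feature semiquantitative clinical
    priority score, and Weibull time-to-onset analysis. Includes a
    synthetic FAERS bundle generator with known ground truth for
    end-to-end validation, and a staged, resumable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
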