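Package: estroscreen
Title: Quantitative High-Throughput Screening Pipeline for
    Estrogen-Driven Growth Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 384-well quantitative high-throughput
    screens (qHTS) that identify compounds inhibiting estrogen-stimulated
    growth of endometrial stromal cell lines. Provides plate-layout and
    cell-count data models, per-plate normalization to vehicle (DMSO)
    controls with 3-SD control-outlier removal, assay quality control
    (Z-prime factor, percent coefficient of variation, QC-compound
    acceptance rules), the percent estrogen-driven inhibition (%E-DI)
    statistic with adaptive mean + 2.5 SD hit thresholding, a
    vehicle-toxicity triage, four-parameter logistic dose-response
    fitting with IC50 adjudication and lead-compound designation, and a
    seeded synthetic screen generator that emulates the paired
    vehicle/estrogen plate design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
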