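Package: faerspv
Title: Pharmacovigilance Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous adverse-event
    reports in the quarterly ASCII dialect of the FDA Adverse Event Reporting
    System (FAERS). Reads and validates the DEMO/DRUG/REAC/THER/OUTC tables,
    deduplicates case versions by the FDA-recommended rule, restricts to
    primary-suspect drug reports via synonym screening, and computes four
    signal-detection statistics on 2x2 contingency tables: the reporting odds
    ratio (ROR), the proportional reporting ratio (PRR) with a chi-squared
    statistic, the Bayesian confidence propagation neural network information
    component (IC with IC025), and a closed-form empirical Bayes geometric mean
    (EBGM with EBGM05), together with the standard positivity criteria.
    Includes sex- and age-stratified detection, volcano-plot data for sex
    contrasts, time-to-onset binning, demographic summary tables, and a seeded
    synthetic FAERS-like data generator with planted disproportionality for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
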