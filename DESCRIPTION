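Package: growthfeedback
Title: Growth-Mediated Feedback Analysis of Antibiotic Dose-Response Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of how growth-mediated feedback, acting
    through growth-rate-dependent expression of an antibiotic's target enzyme,
    shapes the antibiotic dose-response curve. Provides windowed log-linear
    growth-rate and reporter-expression quantification from plate-reader time
    series, Hill dose-response fitting with dose-sensitivity estimation, IC90
    contour and fold-change analysis of checkerboard assays, a reduced
    proteome-allocation growth model with drug-target binding (motivated by
    trimethoprim inhibition of dihydrofolate reductase), construction and
    two-stage fitting of growth-rate-dependent target-regulation surfaces,
    in-silico rewiring of the feedback loop, gene-deletion screen correlation
    statistics with bootstrap errors, and a self-consistent synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
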