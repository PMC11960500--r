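Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for FDA Adverse Event Reporting System
    (FAERS) style spontaneous-report data. Reads the quarterly "$"-delimited
    ASCII tables (DEMO/DRUG/REAC/THER), deduplicates cases, filters to a focal
    suspect drug, and builds drug-event 2x2 contingency tables at MedDRA
    Preferred Term or System Organ Class level. Computes four complementary
    disproportionality statistics - the reporting odds ratio (ROR) with
    lognormal confidence interval, the proportional reporting ratio (PRR) with
    Pearson chi-square, the Bayesian confidence propagation neural network
    information component (IC) with a Monte-Carlo lower credibility bound, and
    the DuMouchel multi-item gamma-Poisson shrinker (MGPS) empirical Bayes
    geometric mean (EBGM) with its fifth posterior percentile - and applies
    joint signal criteria. Includes stratified, cumulative-temporal and
    time-to-onset analyses, a calibrated synthetic FAERS generator for fully
    reproducible testing, and a utility that reconstructs contingency tables
    from published statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
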