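Package: faersignal
Title: Disproportionality Signal Mining for FAERS-Style Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for post-marketing
    pharmacovigilance signal detection on FDA Adverse Event Reporting
    System (FAERS) quarterly-extract-style data. Reads the "$"-delimited
    DEMO/DRUG/REAC/OUTC/THER tables and deleted-case lists, applies
    case-level deduplication (latest FDA receipt date, then largest
    report identifier), builds target-drug cohorts from primary-suspect
    drug mentions, aggregates MedDRA preferred terms to system organ
    classes, and computes four disproportionality statistics per
    drug-event 2x2 table: the reporting odds ratio (ROR), the
    proportional reporting ratio (PRR), the Bayesian confidence
    propagation neural network information component (IC with E(IC),
    V(IC) and IC025), and the observed-to-expected relative reporting
    ratio (EBGM) with 95% confidence intervals and standard signal
    thresholds. Ships a synthetic FAERS-like data generator with known
    ground-truth reporting-rate multipliers so every pipeline stage is
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
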