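Package: abubench
Title: Practice-Level Benchmarking of Antibiotic Use in Cats and Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a national-style benchmarking pipeline for antibiotic
    use (ABU) in companion-animal veterinary practices. Computes the
    practice-level antibiotic treatment indicator (pATI) -- therapy days times
    number of active substances times animals treated, summed over
    prescriptions and normalised by the annual number of consultations --
    separately per species, year and antibiotic scope (all antibiotics or
    critical antibiotics only). Builds percentile-based signal (75th) and
    action (95th) thresholds within practice-type strata, classifies practices
    into four use categories, produces per-practice benchmark reports and
    cohort summaries, and compares group quantiles with a cluster bootstrap.
    Ships a seeded generator of a realistic synthetic prescription cohort so
    the full pipeline can be exercised without access to confidential
    registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
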