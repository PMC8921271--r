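Package: bnetr
Title: Detecting Specific Radiation Damage in Protein Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-atom normalisation of crystallographic B-factors against the
    local packing-density environment of the full crystal lattice (the
    B_Damage metric), and a per-structure summary of aspartate/glutamate
    carboxyl-oxygen damage (the B_net metric) computed as the ratio of
    kernel-density-estimate areas either side of the all-atom median
    B_Damage value. Includes eligibility screening for structure cohorts,
    resolution-windowed percentile ranking, dose-response regression
    summaries, Spearman correlation scans, and a deterministic synthetic
    fixture generator for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
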