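Package: abproteoforms
Title: Quantification of Beta-Amyloid Proteoforms from Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying beta-amyloid (Abeta) proteoforms in brain
    extracts from tandem mass spectrometry data. Implements the label-free
    estimation of the isoAsp7 (isoD7) Abeta fraction from characteristic
    CID fragment-ion intensity ratios via calibration curves built from
    binary norm/iso mixtures, theoretical b/y fragment-mass arithmetic for
    human and murine Abeta, MGF peak-list reading and fragment matching,
    PSM-level proteoform summaries (terminal truncation distributions, PTM
    site occupancies, missed-cleavage accounting, accumulation time series),
    cohort trend statistics (Kendall tau-b, Mann-Whitney U, z-score
    outliers, age-phase grouping), and a synthetic-data generator that
    emulates a 5xFAD-like ageing cohort so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
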