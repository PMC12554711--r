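Package: eegprognosr
Title: Pre/Post Resting EEG Biomarkers and Treatment-Response Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for paired (pre/post treatment)
    resting-state EEG studies on the 16-lead 10-20 montage: band-limited
    feature extraction (approximate, sample and permutation entropy, Welch
    band power, distribution moments) across the five canonical frequency
    bands, paired pre/post significance testing per indicator and channel,
    correlation of feature changes with sleep-scale (PSQI/ISI) score
    changes, responder rates, scalp topographies, and a leave-one-out
    support-vector-regression prognostic model validated by a permutation
    test. Includes a seeded synthetic-cohort generator (band-limited
    oscillations over 1/f background with planted, score-linked
    post-treatment amplitude effects) so the whole pipeline is testable
    without clinical recordings, plus EDF and CSV recording I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
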