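Package: seizedefer
Title: Seizure Detection Post-Processing with a Deferral Option and
    Low-Trust Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-processing toolkit for long-term EEG seizure detection
    from per-segment classifier outputs.  Converts margin-classifier
    decision distances into calibrated confidences by temperature
    scaling, computes nearest-neighbour distance-ratio trust scores,
    raises 10-s seizure flags from 2-s segment predictions, filters
    untrustworthy predictions before flagging (low-trust filtering),
    partitions recordings into reviewable segments and defers the
    least-confident fraction to a perfect human annotator, and scores
    everything with event-based metrics (detection sensitivity, false
    detection rate per 24 h, PPV, F1, detection delay).  Includes the
    nested and leave-one-patient-out cross-validation harnesses used to
    choose the filtering percentage, and a synthetic multi-patient
    cohort generator so the whole pipeline is testable without access
    to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
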