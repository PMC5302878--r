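Package: stemsound
Title: Acoustic Monitoring of Cementless Hip-Stem Implantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hammer strikes in intraoperative audio recordings of
    cementless femoral stem implantation, sums the final five strike
    waveforms, computes an FFT magnitude spectrum in dB, extracts the
    difference between the ~7 kHz and ~4 kHz band peaks, classifies each
    case as acoustic Pattern A or B, detects A-to-B fracture transitions
    across the strike sequence, and evaluates the pattern's diagnostic
    accuracy (sensitivity, specificity, PPV, NPV with Wilson intervals,
    chi-squared, Fisher and Welch tests) against complication outcomes.
    Includes a seeded damped-sinusoid impact-sound simulator for strike
    trains and modal taps with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
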