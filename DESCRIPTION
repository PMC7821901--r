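Package: locostop
Title: Locomotor Stop and Start Event Analysis for Miniscope Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse micro-endoscopic calcium imaging recorded during
    spontaneous locomotion. Computes oriented locomotor speed from body-landmark
    tracking, detects stop, long-stop and start events with rule-based criteria,
    normalises, smooths and deconvolves GCaMP calcium traces, tests per-cell
    event responses against shuffled event times, estimates per-event activation
    probabilities, classifies cells as excited, inhibited or uncorrelated,
    compares cell-class composition between groups with the Freeman-Halton
    exact r x c test, and decodes the locomotor state from population activity
    with a jack-knifed linear support-vector machine. Includes a synthetic
    behaviour-plus-calcium generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
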