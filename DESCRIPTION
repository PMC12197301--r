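Package: salivaflow
Title: Estimating Saliva Secretion from Throat-Microphone Swallowing Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the amount of saliva secreted from the
    sound stream of a wearable throat microphone. Recordings are trimmed
    into candidate sound events with an amplitude-envelope threshold and a
    139.5 ms silence-gap rule, events are classified as swallow versus
    non-swallow by convolutional models fed either short-time Fourier
    spectrograms or complex-Gaussian (gaus5) wavelet scalograms, swallow
    timings over a 5-minute window are summarised into five timing
    features, and grams of saliva secreted per 30 s are estimated by ridge
    regression. A Dawes-type oral-clearance simulator and a swallow-sound
    synthesizer generate fully reproducible surrogate data so every stage
    can be exercised and evaluated without access to recordings of human
    subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
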