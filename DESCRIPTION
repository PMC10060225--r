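Package: ieegpower
Title: Multitaper Spectral Contrasts and Bootstrap ROI Statistics for
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for drug-condition band-power contrasts in
    intracranial (stereo-)EEG. Implements signal conditioning (zero-phase
    line-noise notch, anti-aliased resampling, linear detrending, channel
    exclusion, adjacent-pair bipolar re-referencing), multitaper spectral
    estimation with discrete prolate spheroidal sequence (DPSS) tapers built
    from first principles, condition-mean power spectral densities and band
    contrasts in decibels, anatomical grouping of contacts into coarse
    regions of interest, and channel-pooled percentile-bootstrap confidence
    intervals with overlap-zero classification. A synthetic multi-subject
    iEEG generator with known injected band effects (1/f background, line
    noise, condition-dependent oscillations) makes the whole pipeline
    testable without patient data.
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
    jsonlite,
    purrr,
    readr,
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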