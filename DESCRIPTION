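Package: blinkfuse
Title: Synchronization-Based Fusion of EEG and Eye-Blink Signals for Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for decoding task conditions from blink-locked EEG. Detects
    the eye-blink component in a channel decomposition, cuts blink-locked
    epochs, estimates the temporal offset between the blink peak and the
    post-blink global-field-power (GFP) peak, and shifts the blink signal into
    register with the evoked EEG. Fuses EEG principal components with the
    aligned blink series by concatenation (pcEEG+) or by canonical correlation
    analysis, then decodes conditions with sliding-window linear support vector
    machines, temporal generalization matrices, paired t-tests with false
    discovery rate correction, and extreme-pixel permutation tests. Includes a
    fully parameterized synthetic EEG generator with ground truth so every
    stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
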