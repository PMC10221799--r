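Package: emgtwin
Title: Desk-Scale Digital Twin of a Wrist-Worn Surface EMG Acquisition System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-channel wrist-worn surface electromyography
    (sEMG) acquisition system end to end: synthetic sEMG generation with
    burst envelopes, fatigue progression and realistic interference; the
    three-stage analog conditioning chain (instrumentation amplifier with
    passive high-pass, fourth-order Butterworth low-pass, active twin-T
    notch) modelled as continuous-domain transfer functions; a 16-bit
    bipolar successive-approximation ADC with a 112-bit framed binary
    protocol including parity checking and resynchronization; and the two
    downstream analyses - muscle-fatigue trend detection from windowed RMS
    and median frequency, and four-class gesture recognition via PCA and a
    distance-ordered binary-tree SVM.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
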