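Package: neurotrain
Title: Machine-Learning Neurometric for EEG-Based Training Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify how trained an operator is from multi-session
    electroencephalography (EEG) and task performance. Implements a complete
    pipeline: synthetic multi-session two-condition EEG and behavioral-log
    generation with known discriminative structure, Butterworth band-pass
    filtering, sliding-window epoching with three-criterion artifact rejection,
    Hanning-windowed power spectra anchored to the individual alpha frequency
    (IAF), automatic-stop stepwise linear discriminant analysis (asSWLDA),
    within- and between-session cross-validated ROC-AUC, the Cognitive
    Stability Index, and a normalized triangle-area training-level metric
    combining mean performance, performance stability and cognitive stability.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
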