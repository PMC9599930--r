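Package: vmdforest
Title: Seizure Detection from EEG with Variational Mode Decomposition,
    Log-Euclidean Covariance Features and Deep Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epoch-based epileptic seizure detector for single- and
    multi-channel EEG. Signals are cut into non-overlapping 4-second epochs and
    decomposed with variational mode decomposition (VMD); modes correlated with
    the raw signal form a time-frequency matrix whose covariance is mapped
    through the matrix logarithm (log-Euclidean metric) and half-vectorized
    into the classification feature. A deep-forest classifier (multigrain
    scanning plus an adaptively grown cascade of random and completely-random
    forests) emits per-epoch seizure probabilities, which are smoothed with a
    moving-average filter, thresholded with parameters tuned on training data,
    and collar-extended into seizure events. Epoch-based (sensitivity,
    specificity, accuracy, G-mean) and event-based (event sensitivity, false
    detections per hour) evaluation, and a synthetic EEG generator with known
    seizure annotations, are included.
License: MIT
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
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
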