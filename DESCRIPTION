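Package: emgdecode
Title: Proportional Finger-Position Decoding from Surface EMG with
    User-Adaptation Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous (proportional) myoelectric control research:
    simulation of multi-channel surface EMG calibration sessions paired with
    data-glove kinematics, time-domain feature extraction (Wilson amplitude,
    autoregressive coefficients, waveform length, log-variance, slope sign
    change), an L2-regularized lagged Wiener filter decoder with exponential
    smoothing, sequential forward sensor selection and hyper-parameter search,
    a simulated closed-loop posture-matching task scored against a Monte-Carlo
    random baseline, and block-wise adaptation analytics (principal-component
    tracking of muscle co-activation patterns, EMG power, output variability,
    paired statistics, and offline-versus-real-time correlation).
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
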