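Package: runcoord
Title: Motor Coordination Indices for Runners from Multichannel EMG and Gyroscope Recordings
Version: 0.1.0
Authors@R:
    person("runcoord", "developers", email = "runcoord@example.org", role = c("aut", "cre"))
Description: Tools to assess runners' motor coordination from synchronous
    multichannel surface electromyography (EMG) and shank-mounted gyroscope
    recordings. Running cycles and stance/swing phases are segmented from
    tibialis-anterior angular-velocity signals (moving-average smoothing,
    autocorrelation cadence estimation, swing-peak detection). EMG channels
    are preprocessed with a Butterworth high-pass and a mains notch filter.
    Two diagnostic indices are computed: the integral amplitude and
    spatiotemporal stability coefficient of muscle EMG profiles (K_EMG),
    built from shortest 90%-energy localization windows and cycle-to-cycle
    stability coefficients, and the left/right muscular-effort symmetry
    coefficient (alpha), built from half-cycle-lagged cross-correlation of
    EMG energy envelopes. A synthetic-session simulator with known ground
    truth supports testing without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
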