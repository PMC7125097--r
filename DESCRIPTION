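Package: autoregwave
Title: Correlation and Wavelet-Semblance Indices of Cerebrovascular Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes correlation-based (PRx, COx, HVx) and wavelet-semblance-based
    (wPRx, wCOx, wHVx) cerebrovascular autoregulation indices from multichannel
    physiological recordings, detects the lower limit of autoregulation (LLA) by
    two-segment piecewise regression of laser-Doppler flux on arterial blood
    pressure, identifies the optimal arterial blood pressure (ABPopt) with a
    Fisher-transformed, binned, multi-window weighted curve-fitting method, and
    provides the paired evaluation statistics (ROC with DeLong's test, paired t,
    Pearson agreement, Bland-Altman). Includes a synthetic piglet-recording
    simulator with known LLA and ABPopt so the whole pipeline is testable with
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
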