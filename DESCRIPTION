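Package: amperest
Title: Real-Time Endpoint Prediction for Amperometric Biosensor Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shortens amperometric biosensor analyses by predicting the final
    (steady-state) current before the device reaches stabilization. The raw
    current trace is smoothed with an exponential moving average, the start of
    the enzymatic decay is detected causally as the minimum of the first
    derivative with spike-restart logic, a one-phase exponential decay model
    is fitted to a short post-onset buffer with a Levenberg-Marquardt solver,
    and the asymptotic current is reported early. Includes a synthetic
    amperogram generator with ground truth, percentage-error evaluation, and
    sweep harnesses over the filter constant and the buffer length.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
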