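Package: toxmix
Title: Binary Mixture Toxicity Prediction and Risk Assessment for Algal
    Growth Inhibition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits constrained four-parameter log-logistic
    concentration-response curves to algal growth-inhibition data,
    predicts binary-mixture toxicity under the concentration-addition
    (Loewe) and independent-action (Bliss) models, scores predictions
    with model deviation ratios, and performs environmental risk
    assessment via MEC/PNEC risk quotients and toxic-unit summation
    across trophic levels. Includes a synthetic concentration-response
    data generator with known truth for parameter-recovery and
    pipeline self-consistency testing, and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
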