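Package: hypericinML
Title: Habitat-Based Prediction of Hypericin Content in Hypericum perforatum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the hypericin content (mg/g dry mass) of Hypericum
    perforatum from thirteen habitat, soil and phenology variables using three
    regression models implemented from scratch: a one-hidden-layer perceptron
    with logistic-sigmoid hidden units trained by Levenberg-Marquardt (or plain
    back-propagation), a Gaussian radial-basis-function network with greedy
    center selection and least-squares output weights, and epsilon-insensitive
    support-vector regression solved by SMO over the convex dual. Includes
    accuracy metrics (MSE, RMSE, MAE, two R-squared conventions), a
    highest-test-R-squared model-selection rule, one-at-a-time sensitivity
    analysis with response curves, a synthetic habitat-data generator
    calibrated to published per-variable summary statistics, and a
    reproducible end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
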