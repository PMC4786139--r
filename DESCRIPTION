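Package: caloFS
Title: Chaotic Antlion Optimization for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper feature selection for biomedical classification built on
    the antlion optimizer (ALO) and its chaotic variant (CALO). A continuous
    population optimizer searches the unit hypercube; positions are thresholded
    into feature masks and scored with a bi-objective fitness combining the
    error of a k-nearest-neighbour classifier on held-out validation data with
    the fraction of features retained. Five chaotic maps (logistic, sinusoidal,
    tent, singer, piecewise) modulate the exploration/exploitation schedule.
    Includes the full evaluation-metric suite (run statistics, test accuracy,
    selection size, Fisher scores), a synthetic-data generator with planted
    informative features, an exhaustive-search oracle for small feature
    spaces, and a reproducible multi-run experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
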