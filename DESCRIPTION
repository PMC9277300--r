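Package: eggweber
Title: Egg Pattern Complexity and Proportional Processing of Egg Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies visual complexity of spotted egg patterns from
    calibrated photographs and tests whether host rejection of foreign eggs
    follows Weber's law of proportional stimulus processing. Provides a
    scale-invariant local feature detector for masked egg images, six
    pattern-complexity traits (feature count, positional, scale and
    orientation dispersion, mean intensity change, and a clustering-based
    group metric), a weighted-sum complexity score whose trait coefficients
    are optimized to predict rejection, and the statistical machinery for
    the analysis: logistic regression with AICc/BIC all-subsets selection,
    likelihood-ratio tests, Nagelkerke R-squared, hierarchical partitioning,
    generalized variance inflation factors, and a scan over the exponent k
    of the generalized Weber statistic |a - b| / b^k with a polynomial
    minimum-AIC estimate and +2-AIC confidence interval. A synthetic-data
    module generates spotted egg images with controllable pattern statistics
    and rejection experiments with a known true Weber exponent, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
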