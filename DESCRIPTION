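Package: dissopt
Title: Neural-Network Surrogate Optimization of Sustained-Release
    Formulations from Dissolution Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing sustained-release hydrophilic matrix
    formulations against a target in vitro dissolution profile. A
    four-factor central composite design defines the training corpus; a
    min-max-scaled single-hidden-layer perceptron trained by
    Levenberg-Marquardt least squares maps excipient levels to percent
    drug released at six sampling times; exhaustive enumeration of the
    composition domain then selects the formulation whose simulated
    profile maximizes the f2 similarity factor against a reference
    profile. Includes a composition-dependent Weibull release simulator
    for generating realistic synthetic dissolution studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
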