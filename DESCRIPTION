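Package: brchoice
Title: Information-Theoretic Bounded-Rational Models of Binary Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits and compares models of two-alternative forced choice with
    three binary stimulus features: the Naive Bayes optimum, bounded-rational
    policies with a single action channel or with three feature-specific
    perceptual channels plus an action channel (solved by Blahut-Arimoto style
    fixed-point iteration), condition-wise logistic regression with a shrinking
    parameter set, and the covariance-orthogonalizing-regularization (COR)
    ridge model. Includes plug-in mutual-information metrics, the
    information-utility efficiency frontier, maximum-likelihood precision
    fitting, half-split cross-validated model comparison, and a synthetic
    subject generator emulating a timed classification experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, MASS, jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
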