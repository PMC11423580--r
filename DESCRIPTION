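Package: rigidr
Title: Prediction Rigidities for Additive Regression Models of Molecular Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the robustness of predictions made by additive
    linear-readout models of molecular properties, such as machine-learning
    interatomic potentials and last-layer readouts of neural networks. The
    package computes the prediction rigidity (PR) of a global prediction, the
    local prediction rigidity (LPR) of per-environment contributions, and the
    component-wise prediction rigidity (CPR) of additive descriptor blocks
    (body orders, length scales), all derived from the generalized
    Gauss-Newton Hessian of a weighted squared loss. It provides inverse-PR
    uncertainty estimates, rigidity-guided greedy dataset augmentation and
    active-learning ranking, trajectory rigidity monitoring, and synthetic
    feature generators that emulate body-ordered degeneracy, short-/long-range
    double counting, and committee-variance protocols, together with a small
    command-line interface and plain-text container formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
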