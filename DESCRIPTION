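Package: confbias
Title: Dissociating Perceptual and Decisional Biases in Confidence Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for separating changes in subjective experience from
    response bias in perceptual decision making with binary confidence
    ratings. Provides a generative signal-detection observer with
    independently controllable perceptual, decisional and confidence-center
    shifts; psychometric curve fitting (probit point of subjective equality,
    quadratic point of maximal uncertainty, linear reproduction match point);
    signal-detection sensitivity and criterion with participant screening;
    one-sided JZS Bayes-factor t-tests with posterior effect-size sampling
    and Savage-Dickey density ratios; encompassing-prior ordinal-constraint
    Bayes-factor model comparison over lattices of group-effect patterns;
    per-subject maximum-likelihood meta-d' and M-ratio with a group-level
    posterior; and an end-to-end pipeline including a sequential
    optional-stopping recruitment simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
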