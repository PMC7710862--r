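Package: mimicolor
Title: Bee Color Perception Modelling for Floral Mimicry Systems
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models flower reflectance spectra in the hexagon color space of
    hymenopteran trichromatic vision, evaluates and fits experience-dependent
    psychometric color-discrimination functions for honeybees, represents
    intraspecific floral color variability with copula-based bivariate
    probability density functions, and runs Monte-Carlo confusion-region
    analyses predicting how reliably a bee pollinator can distinguish a
    rewardless mimic flower from its rewarding model under absolute
    conditioning and successive or simultaneous viewing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    nlme,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
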