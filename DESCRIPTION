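Package: dualframe
Title: Simulation and Design-Effect Analysis of Dual-Frame Targeted
    Household Survey Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and evaluate dual-frame, multistage household
    survey designs of the kind used by the continuous New Zealand Health
    Survey: a stratified area sample of meshblocks drawn with probability
    proportional to a targeted size measure, supplemented by a list sample of
    electoral-roll addresses flagged for Maori descent, with one adult and one
    child interviewed per household. Includes a synthetic-population generator
    with spatially clustered ethnic densities, the deterministic design engine
    (power allocation, targeting factors, selection probabilities), the
    stochastic sampler, weighting and jackknife variance estimation, Kish-rule
    design-effect decompositions across counterfactual designs, and numerical
    optimisation of targeting coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
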