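Package: tdrm
Title: Toxin-Digestive Rate Models of Optimal Diet Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimal diet choice for foragers facing simultaneous digestive
    (indigestible ballast) and toxin constraints, built around a multi-species
    Holling disc equation. Implements the classical contingency model, the
    single-constraint digestive rate model, and the two-constraint
    toxin-digestive rate model with partial prey preferences, together with a
    brute-force grid oracle, regime classification over prey-density
    landscapes, functional-response and diet-composition prediction curves, a
    benthos-survey-to-parameter field pipeline (core densities, allometric
    mass filling, stratified availability correction, dropping-based diet
    reconstruction), a two-stage matrix population projection linking intake
    rate to survival, and seeded synthetic data generators so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
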