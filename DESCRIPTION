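Package: thermalniche
Title: Trait-Based Prediction of Ectotherm Thermal Niches and Climate Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic trait-to-niche modelling for ectotherms. Fits thermal
    reaction norms (Boltzmann-Arrhenius, Gaussian, Sharpe-Schoolfield) to
    per-temperature life-history trait data, derives the temperature-dependent
    intrinsic growth rate in closed form via the Lambert W function, delimits
    the fundamental thermal niche (Tmin, Tmax, Topt) and interspecific niche
    overlap, simulates stage-structured delay-differential population dynamics
    with temperature-dependent developmental delays under density-independent
    and density-dependent growth, and computes closed-form equilibria,
    dominant eigenvalues of the delayed linearization, and recovery times
    after perturbation. Ships fitted parameter sets for the bagrada bug
    (Bagrada hilaris) and the harlequin bug (Murgantia histrionica).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
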