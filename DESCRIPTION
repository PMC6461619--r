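Package: rubberband
Title: Constrained Kinetic-Model Fitting with Class-Weighted Parameter
    Penalties and Model Plausibility Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits ODE kinetic models to heterogeneous experimental data by
    constrained optimization with a real-coded genetic algorithm
    (stochastic ranking, REX crossover, just-generation-gap alternation,
    iterative restart).  Deviations of parameters from their reference
    values are penalized by class-dependent "rubber band" weights that
    encode how well each parameter is known; training data enter as
    inequality constraints on relative fit error.  Competing model
    variants are ranked by model plausibility MP = exp(-f) and compared
    across replicate runs with a rank-sum test.  Includes a reduced
    ammonium transport/assimilation demonstration model with active and
    passive transporter variants, futile-cycle energetics, local
    sensitivity analysis, and a synthetic-data generator for end-to-end
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
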