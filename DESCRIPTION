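Package: flowbo
Title: Two-Stage Bayesian Optimisation of a Biocatalytic Flow Amidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-creation of an autonomous two-stage Bayesian
    optimisation campaign for the enzymatic (Novozym-435) amidation of a
    beta-ketoester in continuous flow. A calibrated response-surface simulator
    of the flow reactor and on-line uHPLC replaces the physical rig, and the
    full computational chain is implemented: multiobjective Thompson-sampling
    Bayesian optimisation over Gaussian-process surrogates, Pareto-front
    analysis with diminishing-returns preferred-point selection,
    linear-program inference of scalarisation weights, scalarised
    mixed-variable Bayesian optimisation with 2D latent-variable solvent
    embeddings, and post-campaign model interpretation via kernel
    lengthscales, latent-space geometry and partial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
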