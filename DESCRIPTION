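Package: hilltopdyn
Title: Hilltopping-Mediated Spatial Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing spatial dynamics of patchily distributed
    insect populations whose adults aggregate on hilltops to mate
    (hilltopping). Provides behaviour-informed landscape connectivity
    indices based on exponential distance-decay kernels (direct
    patch-to-patch, hilltop-routed, and elevation-weighted hilltop-routed),
    hierarchical Bayesian Poisson models of adult counts on hilltops,
    Gompertz autoregressive state-space models of annual patch censuses
    with climate covariates, WAIC-based model comparison, and a stochastic
    metapopulation simulator contrasting random and hilltop-routed
    dispersal via patch occupancy, colonization, extinction and regional
    synchrony summaries. Synthetic-data generators emulate the full survey
    design so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
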