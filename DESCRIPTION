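Package: shadecarbon
Title: Carbon Stocks and Growth-Derived Carbon Gains of Shade Trees in
    Cocoa Agroforestry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing aboveground carbon held by remnant,
    spontaneous, and planted trees in cocoa agroforestry inventories.
    Estimates per-tree carbon from diameter, height and wood density with
    the pantropical allometric power law, aggregates it to per-hectare
    plot stocks by tree cohort, and fits two Bayesian hierarchical
    lognormal models by MCMC (JAGS): a plot-level stock model with cohort
    baselines and standardized socio-environmental covariate effects
    through an exponential link, and a tree-level power-law growth model
    over farmer-reported age with cohort-specific exponents and lognormal
    species random effects. Includes a seeded synthetic-study generator
    that emulates the multi-site inventory design for simulation-based
    parameter-recovery checks, quantile and effect reporting, posterior
    trajectory export, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
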