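Package: colonyopt
Title: Colony-Level Optimization of Division of Labor in Eusocial Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling monogynous eusocial insect colonies as
    economic optimizers. Provides concave task-utility families obeying the
    law of diminishing marginal utility, a full productivity ledger
    (usefulness, competence, gross and net productivity), an exact
    equal-marginal-utility solver for the equilibrium division of labor
    under the one-task-per-ant constraint, perturbation analysis of worker
    loss and task redistribution, colony-level (group) selection simulations
    of novel-caste invasion via a mutational random walk, and in-silico
    biomass proxies and caste-knockout experiments. Scenario configuration
    is read from YAML; all stochastic results are reproducible from a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
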