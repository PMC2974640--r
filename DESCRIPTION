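Package: sfggm
Title: Scale-Free Structure Priors for Decomposable Gaussian Graphical Models
Version: 0.1.0
Authors@R:
    person("sfggm", "maintainers", email = "sfggm@example.org", role = c("aut", "cre"))
Description: Bayesian structure learning for decomposable Gaussian graphical
    models with a scale-free structure prior built on the static (Zipf-weight)
    random-network model. Provides the hyper-inverse Wishart marginal
    likelihood with clique/separator factorization, a Metropolis-Hastings
    sampler over the joint state of graph, prior hyperparameters and node
    labeling, exhaustive-enumeration posteriors for small graphs, posterior
    edge-marginal summaries and power-law exponent estimates, and a simulation
    toolkit that draws labeled trees with prescribed degree-distribution
    ensembles and Gaussian data consistent with their conditional-independence
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
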