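Package: swce
Title: Cost-Efficient Incomplete Stepped Wedge Trial Designs
Version: 0.1.0
Authors@R:
    person("swce", "maintainers", email = "swce@example.org", role = c("aut", "cre"))
Description: Design-stage tools for stepped wedge cluster randomized trials
    with continuous outcomes collected via repeated cross-sections. Computes
    the generalized least squares variance of the treatment effect estimator
    for complete and incomplete designs under discrete-time decay,
    block-exchangeable, or exchangeable within-cluster correlation
    structures; asymptotic power of the two-sided Wald test; total trial
    cost including cluster, participant, and data-collection restart costs;
    and cost efficiency. A greedy search iteratively removes sequence-period
    cells to identify the most cost-efficient incomplete design subject to a
    minimum power constraint, and a correlation-grid "superset" procedure
    handles uncertainty in the correlation parameters. Includes a
    configuration-file driven command line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
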