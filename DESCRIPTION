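Package: trajex
Title: Trajectory Exploration of Short Time-Series Expression Data
Version: 0.1.0
Authors@R: person("trajex", "maintainers", email = "trajex@example.org",
    role = c("aut", "cre"))
Description: Operator suite for exploratory analysis of short time-series
    expression matrices (microarray or sequencing, base-2 log scale):
    replicate and segment aggregation, equi-width trajectory discretization,
    prefix-tree trajectory graphs, shape/identity/k-means clustering of
    expression profiles, shape-based pattern filtering and inverse-pattern
    search, control-versus-treatment dataset differencing, hypergeometric
    association statistics, trajectory volatility and linear-trend scores,
    a synthetic-data generator with planted ground truth, and a scriptable
    command-line front end with a replayable operation log.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
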