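Package: pseudotree
Title: Branching Clinical Trajectories and Pseudo-Time from Mixed-Type Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts branching trajectories and pseudo-time from
    mixed-type tabular datasets, such as registries of clinical observations.
    Ordinal and binary variables are quantified by latent-Gaussian scores and
    optimal scaling, missing values are imputed by low-rank SVD completion,
    and the resulting numeric point cloud is approximated by an elastic
    principal tree learned with topological grammar operations.  The fitted
    tree yields a partition of observations into non-branching segments,
    root-to-leaf trajectories, and a per-observation pseudo-time, which feed
    association statistics (chi-squared with deviation scores, ANOVA, kernel
    and logistic pseudo-time regression) and pseudo-time survival analysis
    (Nelson-Aalen cumulative hazards, Kaplan-Meier curves, Cox regression).
    A metro-map style two-dimensional layout of the tree and the data points
    is provided for visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
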