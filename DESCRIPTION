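Package: covnet
Title: Structural Covariance Network Analysis for Multisite Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-wise structural covariance networks from regional
    cortical thickness and subcortical volume data, computes weighted
    graph-theoretical metrics (clustering coefficient, characteristic path
    length, small-world index) normalized against degree- and
    weight-preserving rewired null networks, and compares patients to
    controls across sites with density-wise t-tests, Cohen's d maps, and
    multivariate Hotelling T-squared topology maps. Spatial associations
    between topology-change maps and gene-set expression maps are assessed
    with spin permutation tests on a merged cortical/subcortical sphere,
    variogram-matching surrogate maps, and random-gene permutation nulls,
    including cell-type specificity enrichment. A synthetic-data module
    generates multisite cohorts with planted covariance effects and
    spatially autocorrelated expression matrices so the full pipeline can
    be exercised end to end without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    MASS,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
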