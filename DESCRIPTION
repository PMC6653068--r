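Package: lupustraj
Title: Time-Aware Clustering and Regression of Longitudinal Lupus Biomarker Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for time-aware analysis of longitudinal clinical-registry
    cohorts in systemic lupus erythematosus (SLE). Provides magnitude-based
    Euclidean and multivariate open-end dynamic-time-warping distances between
    patient biomarker trajectories, agglomerative hierarchical clustering with
    dendrogram height cuts and internal validity indices (connectivity, Dunn),
    classical and isotonic multidimensional scaling, time-agnostic and
    time-lagged linear models of disease activity under leave-one-patient-out
    cross-validation with patient-level bootstrap model comparison, odds-ratio
    association of cluster labels with binary clinical characteristics, and a
    synthetic registry generator with planted group structure for end-to-end
    validation without access to real registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
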