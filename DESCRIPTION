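Package: surfSCN
Title: Structural Covariance Networks from Parcellated Cortical Surface Area
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction and comparison of structural covariance networks
    (SCNs) built from parcellated cortical surface area. Provides atlas
    reduction by Ward hierarchical clustering of parcel partial correlations
    with composite quality/consistency selection of the cluster count,
    ComBat-style scan-site harmonization, per-group partial-correlation
    networks with sign-restricted subnetworks, weighted global graph metrics
    including a Jensen-Shannon edge-weight complexity index, spherical
    geodesic distances, small-world propensity against lattice and random
    null models, smooth distance-weight group modelling, permutation-based
    inference with jackknife standard errors, optimal group matching, and a
    seeded synthetic-data generator emulating the covariance structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    mgcv,
    mclust,
    cluster,
    nortest,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Clustering, StatisticalMethod
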