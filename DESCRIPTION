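Package: kvclust
Title: Quantitative Clustering Metrics for Scaffold-Mediated Kv Channel Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based quantification of scaffold-protein-mediated voltage-gated
    potassium (Kv) channel clustering. From two-channel fluorescence micrographs
    (channel-associated red signal, scaffold-associated green signal) and a cell
    mask, the package detects clustering sites by local-maximum spot counting,
    segments them by intensity thresholding, and computes five per-cell clustering
    metrics: normalized surface expression, clusters per unit area, fraction of
    channels in clusters, cluster area, and cluster channel density (background
    corrected integrated signal per unit area). A binomial hetero-tetramer
    composition model links the transfected high-affinity subunit fraction to the
    expected cluster channel density, and a statistical cascade (Kolmogorov-Smirnov
    / Levene assumption checks, ANOVA / Welch / Kruskal-Wallis selection, Tukey
    post-hoc, linear regression) reproduces the study-level inference. A synthetic
    scene generator renders ground-truth-annotated images so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    igraph,
    car,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    nortest,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
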