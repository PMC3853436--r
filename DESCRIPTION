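Package: mirhubnet
Title: Disease-Subtype miRNA Discovery from Dual Mutual-Information Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies disease-subtype-related miRNAs by building two
    miRNA-miRNA interaction networks -- one from miRNA expression profiles and
    one from a reconstructed "activity" dataset that summarises each miRNA's
    target mRNAs by their first principal component -- and intersecting the
    topological hubs of the two networks. Mutual information between miRNA
    profiles is estimated with the Kraskov-Stoegbauer-Grassberger k-nearest
    neighbour estimator and indirect edges are pruned with an ARACNE-style
    data-processing-inequality rule. Includes a permutation-based SAM-style
    differential expression filter, Poisson-null hub calling, a validation
    battery (cross-validated subtype classifiers, random correlation test,
    global test, K-means plus log-rank survival comparison) and a synthetic
    dual-profiling data generator with planted ground truth so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    survival,
    e1071,
    randomForest,
    class,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
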