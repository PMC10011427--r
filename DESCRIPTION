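Package: dricluster
Title: Medoid-Based Deviation Ratio Index for Selecting the Number of Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects the number of clusters in categorical, numerical or
    mixed-type data with the medoid-based deviation ratio index (DRI), a
    criterion computed from the n x k matrix of object-to-medoid distances
    rather than the full pairwise distance matrix.  Final medoids are produced
    by a block-based k-medoids algorithm that seeds initial medoids from
    blocks of objects ordered by per-row standard deviation.  Also provides
    the distance-based variance ratio criterion (Calinski-Harabasz),
    silhouette widths and medoid shadow values as comparators, dissimilarity
    functions for mixed data (simple matching, Canberra, a generalized Gower
    distance), min-max and ordinal rank standardization, synthetic benchmark
    generators for cluster-number recovery experiments, and a small command
    line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
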