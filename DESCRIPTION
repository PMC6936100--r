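Package: comorbnet
Title: Comorbid Disease Prediction via Geometric Embedding of the Interactome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts comorbid disease pairs from a protein-protein
    interaction network. The interactome is embedded into an m-dimensional
    geometric space using classical double-centered eigen-embedding of
    geodesic distances (multidimensional scaling on graph distances) or
    minimum curvilinear embedding over minimum-spanning-tree distances
    (centered MCE and non-centered ncMCE), optionally with pathway-derived
    edge weights. Each disease pair's gene module is fingerprinted as an
    (m+3)-dimensional feature vector (per-dimension module projections plus
    average degree, average betweenness centrality, and average pathway
    count) and classified as comorbid versus non-comorbid with support
    vector machines or random forests, benchmarked against the
    module-separation baseline. Includes a synthetic-data generator with
    planted comorbidity structure for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    e1071,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
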