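Package: mirhic
Title: Enrichment of miRNA Target Sets in Hierarchical Gene Co-Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers perturbed microRNA regulatory networks from a case/control
    gene expression matrix and a weighted miRNA-target network. Differentially
    expressed genes are organized into multi-scale co-expression signatures by
    average-linkage hierarchical clustering with a Fisher-z correlation cutoff;
    target-set enrichment is scored inside every signature by summing
    discretized target-prediction context scores, and significance is assessed
    against score-stratified bipartite permutations of the target network, with
    a nested empirical p-value correcting the minimum-over-signatures bias.
    Ships the flat-signature (miRDeG), k-means signature (miRKM) and
    hypergeometric baselines, plus a seeded synthetic-data generator with a
    planted regulator for calibration and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
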