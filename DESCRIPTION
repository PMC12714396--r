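Package: mmdwalk
Title: Microbe-Drug Association Prediction via Random Walks on a
    Microbe-Metabolite-Drug Heterogeneous Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microbe-drug associations by embedding a typed
    microbe-metabolite-drug heterogeneous graph. The graph couples microbes
    and drugs through a shared metabolite space (production/consumption,
    reaction-pair and drug-metabolite edges) and through similarity-gated
    same-type edges built from Gaussian interaction profile kernels,
    molecular fingerprints, genome distances and phylogeny. A random walker
    with node-type-tailored transition laws (a sigmoid-gated choice between
    same-type and metabolite moves, and an EM-estimated edge-type transition
    matrix at metabolite nodes) generates a corpus that a node-type-aware
    skip-gram model turns into embeddings; a gradient-boosted tree
    classifier on Hadamard pair features scores candidate associations.
    Includes a planted-partition simulator, a cross-validation harness and
    the usual link-prediction metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    ChemmineR,
    jsonlite,
    pROC,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
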