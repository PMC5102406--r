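Package: fragnet
Title: Fragment-Based Ensemble Bayesian Network Inference for
    Mixed-Culture Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs consensus gene networks from two-color
    microarray, metabolite and culture-condition data by enumerating and
    scoring local linear-Gaussian network fragments (plain,
    switched-conditional and linearly-conditional), sampling an ensemble
    of 1,000 acyclic networks, and extracting the edges whose ensemble
    frequency exceeds a slope-minimum cutoff.  Includes the probe-level
    preprocessing used for pangenome arrays (geometric spot averaging,
    background filtering, correlation-based ortholog collapsing), censored
    metabolite handling with paired switches and an eighth-root transform,
    strain-lineage assignment and edge classification, an exhaustive
    small-instance posterior oracle for validating the sampler, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
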