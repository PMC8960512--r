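Package: scnet
Title: Structural Covariance Network Analysis for Multiple Sclerosis MRI Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level structural covariance network analysis of regional
    grey-matter fractions, as used in multiple sclerosis neuroimaging.
    Builds weighted undirected association graphs from Spearman
    correlations (negative edges zeroed), computes the standard nodal and
    global graph-theory parameter set (degree, strength, path length,
    clustering, global and local efficiency, within-module degree z-score,
    participation, transitivity, modularity, assortativity,
    small-worldness), and compares groups with label-permutation tests
    using a 95 percent confidence-interval decision rule and
    Benjamini-Hochberg false-discovery-rate correction for nodal maps.
    Includes a local-neighbourhood lesion-filling operator for 3-D
    volumes with phantom generation and artefact scoring, and a synthetic
    cohort simulator with paired original and lesion-filled arms for
    power and validity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    withr,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
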