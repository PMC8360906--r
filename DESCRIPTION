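Package: epimech
Title: Vertex-Model Mechanics of Epithelia with Hyper-Contractile Cell Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static vertex-model simulation of a planar epithelium
    containing a cluster of hyper-contractile cells, together with the
    measurement and inference tools needed to analyse it: cell shape tensors,
    principal axes and circularity; ring (graph) distance to the cluster and
    shape orientation relative to the cluster boundary; the isotropic
    cell-level stress Peff; 1D Wasserstein comparison of orientation
    distributions and a grid search that infers the cluster's cortical
    contractility increase from them; Kelvin-Voigt fitting of laser-ablation
    recoil traces; and deterministic synthetic-data generators (traced
    polygons, recoil traces, division events) that emulate confocal-derived
    measurements so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
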