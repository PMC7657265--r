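Package: hierpath
Title: Tracing Communication Paths Through Cortical Hierarchies
Version: 0.1.0
Authors@R:
    person("Hierpath", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-stage pipeline for studying how the unimodal-transmodal
    cortical hierarchy shapes communication in structural brain networks.
    Stages cover group-consensus connectome assembly from subject matrices,
    diffusion-map estimation of the functional hierarchy gradient, all-pairs
    weighted shortest paths with full path reconstruction, hierarchy-labelled
    path motifs, per-node slope and turning-point flow statistics, positional
    and multi-hop transition-probability matrices, beta-mixed spatial and
    hierarchical greedy navigation, distance-binned degree-preserving rewiring
    and spherical-rotation (spin) permutation nulls, simple graph measures,
    and a synthetic multi-subject cohort generator that makes the whole
    pipeline testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
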