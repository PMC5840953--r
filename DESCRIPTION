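Package: sustsig
Title: Inference of Sustained Signaling Subnetworks from Differential
    Expression and Signed Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers intracellular signaling subnetworks that are likely to be
    constantly activated or inhibited under a persistent stimulus (for
    example chronic inflammation) by integrating a signed directed signaling
    interactome with booleanized differential-expression calls. A dummy root
    node standing in for the unknown stimulus is attached to all upregulated
    receptors and ligands, interactome edges are weighted by the
    compatibility between interaction sign and expression states, and a
    rooted directed Steiner arborescence connecting the root to every
    differentially expressed transcription factor is solved exactly (dynamic
    programming over terminal subsets), by brute force (testing oracle), or
    by a deterministic shortest-path heuristic. Solution trees are
    decomposed into per-receptor subnetworks with up/down transcription
    factor counts and compared across regions or conditions. A seeded
    synthetic-data generator plants receptor-to-TF pathways with consistent
    expression states so the whole pipeline is testable by receptor
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
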