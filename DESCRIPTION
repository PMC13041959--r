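Package: xlmstools
Title: Crosslink-Guided Scoring and Analysis of Integrative Structural Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for validating and ranking candidate structural models of
    protein complexes against crosslinking mass spectrometry (XL-MS) data.
    Reads candidate models (PDB), crosslink spectrum match tables and FASTA
    sequences; deduplicates spectrum matches into unique residue-pair
    crosslinks; measures Euclidean and grid-based solvent-accessible surface
    distances between crosslinked lysine alpha-carbons; scores and ranks
    models by crosslink satisfaction under the DSSO 37 Angstrom criterion;
    exports satisfied crosslinks as distance restraints for refinement and
    docking engines; and produces residue contact maps, lysine-lysine
    distance heatmaps and rigid-body (Kabsch) superpositions. A synthetic
    data module generates multi-chain models with ideal backbone geometry,
    decoy ladders with known rigid perturbations, and crosslink tables with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
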