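Package: gcabm
Title: Multiscale Agent-Based Simulation of the Germinal Center Reaction
    and B-Cell Receptor Repertoires
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seeded, configurable multiscale simulator of a single
    germinal center (GC) reaction. An agent-based model of centroblast and
    centrocyte dynamics in the dark and light zones is coupled, per cell,
    to an immunoglobulin heavy-chain nucleotide sequence mutated through a
    somatic-hypermutation fate tree, to a continuous four-dimensional
    shape-space affinity model, and to a three-equation BLIMP1/BCL6/IRF4
    gene-regulatory network that drives plasma-cell differentiation. The
    simulator emits DNA- and RNA-based B-cell receptor repertoires, clonal
    lineage forests in Newick format, and clonal diversity statistics
    (D50, Berger-Parker, Pielou evenness, Chao1), and includes a
    standalone repertoire-statistics path for AIRR-style rearrangement
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, ImmunoOncology, Sequencing, SystemsBiology
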