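Package: coildiverge
Title: Domain-Resolved Sequence Divergence and Desk-Scale Phylogenetics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compares the evolutionary divergence of a protein's functional
    domain against the whole protein across species groups. Provides pairwise
    percent-identity matrices (whole-sequence and region-restricted), a
    windowed heptad-propensity coiled-coil caller, lineage-specific residue
    detection, the conservation-distance cluster statistic with slope-1
    diagonal classification of domain-conserved versus domain-accelerated
    species pairs, and desk-scale tree inference (neighbor joining, column
    bootstrap, majority-rule consensus, Fitch parsimony scoring). A sequence
    evolution simulator (HKY85 with discrete-gamma rate variation and
    region- and lineage-specific rate multipliers) generates mammal-like
    orthologue datasets so that every stage of the analysis is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
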