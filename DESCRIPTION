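Package: ssp
Title: Successor Sequence Prediction from Ancestral Protein Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate "next" amino-acid substitutions for a target
    protein by extrapolating per-site evolutionary trends along the root-to-target
    path of a rooted phylogenetic tree carrying reconstructed ancestral sequences.
    Each alignment column is turned into a residue trajectory, projected through
    nine curated physicochemical descriptor scales (molecular weight, melting
    point, residue volume, hydrophobicity, flexibility, transfer free energy,
    electrical effect, polarity, isoelectric point), fitted with a
    distance-weighted linear trend, and extrapolated one evolutionary step beyond
    the target. Predictions are scored (sequentiality, fluctuation, break-trend),
    ranked, aggregated across trees, and bundled into mutation-agreeing and
    site-agreeing tiers. Includes homolog filtering and sequence-file
    partitioning utilities for dataset preparation, a synthetic-history generator
    for testing, and mutational-enrichment evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
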