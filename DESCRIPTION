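Package: AlaScanRNP
Title: Computational Alanine Scanning of Protein-RNA Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-RNA complex structures and for
    predicting amino-acid hotspots by computational alanine scanning.
    Reads PDB coordinate files, detects interface contacts and computes
    buried surface area with a native Shrake-Rupley solvent-accessible
    surface implementation, classifies the bound RNA into structural
    motif classes (single strand, duplex, hairpin, complex fold), trains
    a distance-dependent knowledge-based potential with a decoy-derived
    reference state, and scores every interface residue by the change in
    log-score upon alanine truncation, normalised per interface to a
    dimensionless interaction score. Residues with interaction scores
    above 2 are called hotspots, those between 1 and 2 warmspots.
    Includes dataset-curation filters (resolution, chain lengths,
    modified-base content, sequence redundancy) and a seeded generator
    of synthetic protein-RNA complexes used for training, testing and
    examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
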