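Package: trpfinger
Title: Conservation Fingerprints and Structural Core Analysis for TRP Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence- and structure-conservation analysis for transient
    receptor potential (TRP) cation channels and related six-transmembrane
    proteins. Scans multiple sequence alignments for highly conserved columns
    with aromatic-class (Phe/Tyr) grouping, scores sequences against the
    twelve-slot Group-I TRP residue fingerprint, ranks alignment columns by
    profile-emission Shannon entropy, computes ensemble distograms (mean,
    variance and normalized variance of residue-residue distances across
    structure collections), detects core-facing aromatic residues in the
    TM1-TM4 helix bundle and clusters them at a distance threshold, detects
    intra- and inter-subunit residue contacts, and fits an asymmetric
    pseudo-likelihood direct coupling analysis (Potts) model with
    average-product-corrected coupling scores. Includes synthetic-data
    generators (structured alignments, Potts-sampled alignments and ideal
    helix-bundle coordinate ensembles) with machine-readable ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
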