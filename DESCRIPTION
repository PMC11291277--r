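Package: paleozooms
Title: ZooMS Identification, Collagen Deamidation and Phyloproteomic
    Placement for Palaeoproteomic Bone Assemblages
Version: 0.1.0
Authors@R:
    person("BKC", "Analysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the desk-scale analysis chain used in
    palaeoproteomic studies of Pleistocene bone assemblages: construction
    and querying of taxonomy-aware ZooMS (zooarchaeology by mass
    spectrometry) collagen peptide-marker databases with in-silico tryptic
    digestion and monoisotopic mass prediction; MALDI-TOF peak-list
    processing and triplicate replicate merging; marker matching and
    taxonomic assignment with lowest-consistent-taxon logic; glutamine
    deamidation estimation from isotope envelopes for the COL1a1 508-519
    and 435-453 peptides with per-layer bootstrap summaries; target-decoy
    FDR filtering of peptide-spectrum matches and majority-consensus
    protein sequence reconstruction; maximum-likelihood phylogenetic
    placement under the Dayhoff amino-acid model with nonparametric
    bootstrap; NISP-based faunal assemblage statistics with Shannon and
    Simpson diversity indices; and seeded synthetic-data generators with
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
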