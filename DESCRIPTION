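Package: helminthAMP
Title: Computational Discovery of Antimicrobial Peptide-Like Peptides in
    Helminth Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for predicting antimicrobial peptide-like
    peptides (AMP-LPs) from nematode and flatworm predicted proteomes.
    Implements precursor-level filtering (deduplication, ambiguous-residue and
    length filters), excision of candidate mature peptides from signal-peptide
    and dibasic propeptide cleavage sites, majority-vote consensus over an
    ensemble of AMP predictor calls, all-vs-all local alignment with
    Karlin-Altschul bit scoring and connected-component sequelog grouping,
    multi-stage curation (known-AMP exclusion, Gene Ontology blocklist,
    group-length and cysteine-class triage, expression flags), physicochemical
    characterisation (monoisotopic and average mass with post-translational
    modifications, net charge, hydrophobicity, MIC unit conversion), and
    LC-MS/MS validation support (peptide-spectrum-match confidence tiers,
    theoretical b/y fragment ladders, consecutive-ion checks, precursor
    sequence coverage). Includes a seeded synthetic-proteome generator with
    ground-truth tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, SequenceMatching, Classification
RoxygenNote: 7.3.3
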