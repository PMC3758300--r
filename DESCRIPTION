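Package: plastkit
Title: Structural and Evolutionary Analysis of Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of chloroplast (plastid)
    genomes: detection of the inverted-repeat pair and derivation of the
    quadripartite LSC/IRb/SSC/IRa partition with gene-to-junction distance
    profiles; codon counting and relative synonymous codon usage (RSCU) over
    protein-coding exons; exact-identity repeat discovery and classification
    into tandem, direct and inverted families; conservation-based prediction
    of C-to-U RNA editing sites from homolog protein panels together with
    summary statistics of observed editing; and equal-cost (Fitch) parsimony
    mapping of gene gain, duplication, pseudogenization and loss characters
    onto a fixed phylogeny.  Seeded generators produce synthetic plastomes,
    repeat fixtures and homolog panels for property-based testing, and
    reference tables transcribed from the published coconut (Cocos nucifera)
    chloroplast genome (GenBank KF285453) are shipped as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
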