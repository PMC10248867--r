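Package: kinconform
Title: Conformational-State Classification of Protein Kinase Domain Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies protein kinase domain structures as active or inactive
    from coordinates: spatial DFG placement (DFGin/DFGout/DFGinter) from the
    D1/D2 distances, Ramachandran-region/chi1-rotamer dihedral clusters
    (e.g. BLAminus), the beta3-Lys/alphaC-Glu salt bridge, hydrophobic
    catalytic- and regulatory-spine assembly, nucleotide contacts and
    activation-segment phospho-sites, with Kabsch superposition and iterative
    outlier trimming for inter-structure RMSD.  Also provides the supporting
    sequence and statistics utilities used alongside such analyses:
    p-distance/neighbor-joining phylogenies with bootstrap supports, ORF and
    protein-mass arithmetic, motif scanning, qPCR relative expression by the
    2^-ddCt method, Duncan's multiple range test and Student's t-test, plus a
    synthetic-data generator (toy kinase coordinate models, alignments evolved
    on a tree, Ct tables) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ape,
    seqinr,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
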