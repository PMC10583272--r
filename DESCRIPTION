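Package: ncAAlib
Title: Residue Libraries, IUPAC Atom Naming and Side-Chain Links for
    Non-Canonical Amino Acids in NMR Structure Calculation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for preparing non-canonical amino acids (ncAAs) for NMR
    structure calculation. Implements automatic IUPAC/IUBMB-conformant atom
    renaming of arbitrary amino-acid side chains using Cahn-Ingold-Prelog
    priority rules with a geometric (determinant) tie-break for prochiral
    centres, recognition and excision of capped peptide templates
    (Ace-Ala-X-Ala-NMe and terminal variants), generation of CYANA
    side-chain linkage files (DUMMY-overlap templates, short upper-distance
    restraints and link statements) from pairs of extended residue
    templates, and CNS building-block patching (standard backbone atom-type
    retention, residual-charge absorption and atom-type clash resolution).
    Includes readers and writers for PDB (CONECT-bearing), Mol2, CYANA
    residue library and restraint formats and CCD-style component CIF, a
    programmatic fixture generator for amino-acid graphs with idealised
    geometry, and an independent brute-force CIP oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
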