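Package: strucheck
Title: Sequence and Numbering Consistency Checks for Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies that the amino-acid sequence and residue numbering of a
    protein structure file (PDB format) agree with an up-to-date UniProt
    reference sequence. Extracts the per-chain sequence from ATOM records,
    aligns it globally to the reference with a deterministic Needleman-Wunsch
    implementation, classifies every alignment column (identifier match or
    mismatch, missing reference residues, structure-only insertions), reports
    summary statistics and assessment messages, and writes a residue mapping
    table (TSV/JSON), the alignment (FASTA) and a structure renumbered in
    UniProt coordinates. Includes a deterministic synthetic-fixture generator
    that derives perturbed structure chains from a reference sequence with
    known ground-truth labels, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
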