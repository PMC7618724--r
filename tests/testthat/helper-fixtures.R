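# Small builders for hand-written PDB text.

atom_line <- function(serial, resn, chain, resseq, icode = " ",
                      atom = " CA ", record = "ATOM  ", altloc = " ") {
  sprintf("%s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          record, serial, atom, altloc, resn, chain, resseq, icode,
          serial * 3.8, 0, 0, 1, 0)
}

pdb_text <- function(...) c(..., "TER", "END")

# A fixture with no edits at all: structure == reference, numbering 1..L.
perfect_fixture <- function(len = 40, seed = 1) {
  ref <- make_reference(len, seed)
  apply_edits(ref, edit_plan())
}
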