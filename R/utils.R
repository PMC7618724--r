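# Shared constants and small helpers.

# Standard 20 amino acids, three-letter -> one-letter.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- c(setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE), X = "UNK")

AA20 <- sort(unname(AA_THREE_TO_ONE))

# Reference sequences may additionally carry ambiguity/rare codes.
REF_ALPHABET <- c(AA20, "X", "U", "O", "B", "Z", "J")

# Modified residues mapped to a parent amino acid when explicitly requested;
# these appear as HETATM in most files (e.g. selenomethionine).
AA_MODIFIED <- c(MSE = "M", SEC = "U", PYL = "O")

# Residue names that are never part of a protein polymer; excluded outright
# rather than reported as 'X'.
NON_AA_RESNAMES <- c(
  "HOH", "DOD", "WAT",
  "A", "C", "G", "U", "I", "N",
  "DA", "DC", "DG", "DT", "DI", "DU"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# seq() that returns integer(0) instead of counting down when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Render a structure residue identifier
#'
#' The author residue identifier of a structure residue is its residue number
#' immediately followed by the insertion code, if any (e.g. `"100"`, `"100A"`).
#'
#' @param res_seq Integer residue number(s).
#' @param icode Insertion code(s); `""` or `" "` for none.
#' @return Character vector of identifiers.
#' @export
structure_id <- function(res_seq, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(res_seq, icode)
}
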