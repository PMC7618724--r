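# Fixed-column PDB parsing and rewriting. Only the ATOM section defines the
# polymer sequence; the original lines are retained verbatim so the
# renumbered output touches nothing but the residue-number columns (23-26)
# and the insertion-code column (27).

as_pdb_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read a PDB structure file
#'
#' Parses the ATOM records of a PDB file into per-chain residue sequences.
#' One residue is recorded per distinct (chain, residue number, insertion
#' code) triple, in order of first appearance; alternate-location duplicates
#' collapse to the first atom seen. Only the first MODEL of a multi-model
#' file is read. HETATM records, waters and non-amino-acid polymer residues
#' are excluded; with `include_modified = TRUE`, HETATM records of known
#' modified amino acids (MSE, SEC, PYL) are included and mapped to their
#' parent one-letter code. Unknown three-letter residue names become `'X'`.
#'
#' @param x Path to a PDB file, or PDB content (character scalar or vector
#'   of lines).
#' @param include_modified Include known modified amino acids from HETATM
#'   records (default `FALSE`).
#' @param source_label Free-text label for reporting; defaults to the path
#'   or `"<text>"`.
#' @return An object of class `pdb_structure`: `source_label`, `chains`
#'   (named list of `chain_sequence`), `raw_lines`, `model_number`.
#' @export
read_pdb <- function(x, include_modified = FALSE, source_label = NULL) {
  if (is.null(source_label)) {
    source_label <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) &&
                        file.exists(x)) x else "<text>"
  }
  lines <- as_pdb_lines(x)
  if (!length(lines)) stop("empty structure: no ATOM records found", call. = FALSE)
  rec <- substr(lines, 1, 6)

  # First-MODEL window for multi-model (NMR-style) files.
  scope <- rep(TRUE, length(lines))
  model_number <- NA_integer_
  model_at <- which(substr(lines, 1, 5) == "MODEL")
  if (length(model_at)) {
    first <- model_at[1]
    endmdl <- which(rec == "ENDMDL" & seq_along(lines) > first)
    last <- if (length(endmdl)) endmdl[1] - 1L else length(lines)
    scope <- seq_along(lines) >= first & seq_along(lines) <= last
    model_number <- suppressWarnings(as.integer(substr(lines[first], 7, 14)))
    if (is.na(model_number)) model_number <- 1L
  }

  is_atom <- rec == "ATOM  " & scope
  is_het <- rec == "HETATM" & scope
  idx <- which(is_atom | is_het)
  if (!length(idx)) stop("empty structure: no ATOM records found", call. = FALSE)

  l <- lines[idx]
  res_name <- trimws(substr(l, 18, 20))
  chain <- substr(l, 22, 22)
  res_seq_str <- trimws(substr(l, 23, 26))
  icode <- sub(" ", "", substr(l, 27, 27), fixed = TRUE)

  keep <- rep(TRUE, length(idx))
  keep[is_het[idx]] <- include_modified & res_name[is_het[idx]] %in% names(AA_MODIFIED)
  keep[res_name %in% NON_AA_RESNAMES] <- FALSE
  if (!any(keep)) stop("empty structure: no amino-acid ATOM records found", call. = FALSE)

  bad <- keep & !grepl("^-?[0-9]+$", res_seq_str)
  if (any(bad)) {
    stop("malformed residue number in columns 23-26 at line ",
         idx[which(bad)[1]], call. = FALSE)
  }

  idx <- idx[keep]
  res_name <- res_name[keep]
  chain <- chain[keep]
  res_seq <- as.integer(res_seq_str[keep])
  icode <- icode[keep]

  key <- paste(chain, res_seq, icode, sep = "\r")
  first_of <- !duplicated(key)

  # Same (chain, res_seq, icode) with a different residue name is a genuine
  # duplicate, not an altloc; keep the first and warn.
  name_of_key <- res_name[first_of][match(key, key[first_of])]
  clash <- which(!first_of & res_name != name_of_key)
  if (length(clash)) {
    warning("duplicate residue identifier ",
            structure_id(res_seq[clash[1]], icode[clash[1]]),
            " in chain ", chain[clash[1]],
            " with conflicting residue name; keeping first", call. = FALSE)
  }

  one <- unname(AA_THREE_TO_ONE[res_name])
  one[is.na(one)] <- unname(AA_MODIFIED[res_name[is.na(one)]])
  one[is.na(one)] <- "X"

  chains <- list()
  for (cid in unique(chain)) {
    sel <- chain == cid & first_of
    atom_lines <- split(idx[chain == cid], key[chain == cid])
    # preserve first-appearance order of residues within the chain
    ord_keys <- key[sel]
    residues <- data.frame(
      order_index = seq_len(sum(sel)) - 1L,
      res_seq = res_seq[sel],
      icode = icode[sel],
      res_name = res_name[sel],
      one_letter = one[sel],
      stringsAsFactors = FALSE
    )
    chains[[cid]] <- structure(
      list(chain_id = cid,
           residues = residues,
           sequence = paste(one[sel], collapse = ""),
           atom_lines = unname(atom_lines[ord_keys])),
      class = "chain_sequence"
    )
  }

  structure(
    list(source_label = source_label, chains = chains,
         raw_lines = lines, model_number = model_number),
    class = "pdb_structure"
  )
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("PDB structure [%s]%s\n", x$source_label,
              if (!is.na(x$model_number)) sprintf(" (model %d)", x$model_number) else ""))
  for (ch in x$chains) {
    cat(sprintf("  chain %s: %d residues\n", ch$chain_id, nrow(ch$residues)))
  }
  invisible(x)
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat(sprintf("Chain %s: %d residues\n%s\n", x$chain_id, nrow(x$residues),
              x$sequence))
  invisible(x)
}

#' Extract one chain's sequence from a parsed structure
#'
#' @param model A `pdb_structure` from [read_pdb()].
#' @param chain_id Single-character chain identifier.
#' @return The chain's `chain_sequence`.
#' @export
extract_chain_sequence <- function(model, chain_id) {
  stopifnot(inherits(model, "pdb_structure"))
  if (!chain_id %in% names(model$chains)) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(names(model$chains), collapse = ", "), call. = FALSE)
  }
  model$chains[[chain_id]]
}

#' Write a renumbered PDB file for one chain
#'
#' Rewrites the selected chain's atom records with new residue numbers in
#' columns 23-26 (right-justified) and a blanked insertion code in column 27;
#' every other byte of each retained line is preserved. Residues mapped to
#' `NA` are dropped entirely (with a warning). Records of other chains and
#' non-coordinate records are omitted; a REMARK line names the reference
#' accession the numbering now follows.
#'
#' @param model A `pdb_structure`.
#' @param chain_id Chain to rewrite.
#' @param renumber A [renumber_plan()] or a named integer vector mapping each
#'   structure residue identifier (e.g. `"100"`, `"100A"`) to its new residue
#'   number, with `NA` meaning drop.
#' @param accession Reference accession named in the REMARK line.
#' @param path Optional output file; if given, lines are written there.
#' @return Character vector of output lines (invisibly when `path` is given).
#' @export
write_renumbered_pdb <- function(model, chain_id, renumber,
                                 accession = "REFERENCE", path = NULL) {
  ch <- extract_chain_sequence(model, chain_id)
  map <- if (inherits(renumber, "renumber_plan")) renumber$assignments else renumber
  ids <- structure_id(ch$residues$res_seq, ch$residues$icode)
  missing <- setdiff(ids, names(map))
  if (length(missing)) {
    stop("renumber map lacks entries for residues: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  new_num <- unname(map[ids])
  drop <- is.na(new_num)
  if (any(drop)) {
    warning(sum(drop), " residue(s) removed from the renumbered structure (",
            paste(utils::head(ids[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "", ")", call. = FALSE)
  }
  keep_num <- new_num[!drop]
  if (length(keep_num) && (min(keep_num) < -999 || max(keep_num) > 9999)) {
    stop("formatting error: renumbered residue number outside -999..9999",
         call. = FALSE)
  }
  out <- sprintf("REMARK 999 CHAIN %s RENUMBERED TO %s SEQUENCE POSITIONS BY STRUCHECK",
                 chain_id, accession)
  for (i in which(!drop)) {
    for (li in ch$atom_lines[[i]]) {
      line <- model$raw_lines[li]
      out <- c(out, paste0(substr(line, 1, 22), sprintf("%4d", new_num[i]), " ",
                           substr(line, 28, nchar(line))))
    }
  }
  out <- c(out, "TER", "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
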