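# Reference (UniProt) sequences: FASTA parsing, REST retrieval with a disk
# cache, and the tool's input-size limits.

#' Construct a reference sequence
#'
#' A reference sequence is the up-to-date UniProt sequence for an accession;
#' residue `i` of the sequence carries the UniProt identifier `i` (1-based).
#'
#' @param accession Accession string (free text for synthetic references).
#' @param sequence Amino-acid sequence; uppercased, whitespace stripped.
#' @return An object of class `reference_sequence` with elements `accession`,
#'   `sequence` and `length`.
#' @export
reference_sequence <- function(accession, sequence) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) stop("reference sequence is empty", call. = FALSE)
  letters <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters, REF_ALPHABET)
  if (length(bad)) {
    stop("reference sequence contains invalid letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(accession = as.character(accession), sequence = sequence,
         length = nchar(sequence)),
    class = "reference_sequence"
  )
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("Reference sequence %s: %d aa\n", x$accession, x$length))
  invisible(x)
}

# Pull an accession out of a FASTA header: "db|ACC|name" or the bare first word.
parse_fasta_accession <- function(header) {
  first <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
  if (grepl("|", first, fixed = TRUE)) {
    parts <- strsplit(first, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && nzchar(parts[2])) return(parts[2])
  }
  first
}

#' Read a reference sequence from FASTA
#'
#' Accepts a file path or FASTA text. The file must hold exactly one record,
#' unless `accession` selects one record out of several by its header
#' accession (UniProt-style `db|ACC|name` headers or a bare first word).
#'
#' @param x Path to a FASTA file, or FASTA content as a character scalar
#'   (or vector of lines).
#' @param accession Optional accession used to select one record.
#' @return A [reference_sequence()].
#' @export
read_ref_fasta <- function(x, accession = NULL) {
  path <- NULL
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && !startsWith(x, ">") &&
      file.exists(x)) {
    path <- x
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records found", call. = FALSE)
  accs <- vapply(names(set), parse_fasta_accession, character(1), USE.NAMES = FALSE)
  idx <- 1L
  if (!is.null(accession)) {
    idx <- which(accs == accession)
    if (length(idx) == 0) {
      stop("no FASTA record matches accession '", accession, "'; found: ",
           paste(accs, collapse = ", "), call. = FALSE)
    }
    idx <- idx[1]
  } else if (length(set) > 1) {
    stop("FASTA contains ", length(set),
         " records; supply `accession` to select one", call. = FALSE)
  }
  reference_sequence(accs[idx], as.character(set[[idx]]))
}

#' Serialise a reference sequence as FASTA text
#'
#' @param ref A [reference_sequence()].
#' @param width Line-wrap width.
#' @return FASTA text (single newline-terminated string).
#' @export
ref_to_fasta <- function(ref, width = 60) {
  stopifnot(inherits(ref, "reference_sequence"))
  body <- substring(ref$sequence,
                    seq(1, ref$length, by = width),
                    pmin(seq(1, ref$length, by = width) + width - 1, ref$length))
  paste0(paste(c(paste0(">", ref$accession), body), collapse = "\n"), "\n")
}

#' Validate a UniProt accession string
#'
#' Syntactic check only (UniProtKB accession grammar, with an optional
#' isoform suffix such as `-2`).
#'
#' @param accession Candidate accession.
#' @return `TRUE` or `FALSE`.
#' @export
is_uniprot_accession <- function(accession) {
  grepl(paste0(
    "^([OPQ][0-9][A-Z0-9]{3}[0-9]|",
    "[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})(-[0-9]+)?$"
  ), accession)
}

#' Fetch the current UniProt sequence for an accession
#'
#' Queries the UniProtKB REST endpoint for the accession's FASTA and caches
#' the result on disk (JSON, keyed by accession, with the retrieval date) so
#' repeated runs are reproducible and offline runs can reuse it. The cache is
#' consulted first; with `offline = TRUE` no network request is ever made.
#'
#' @param accession UniProt accession (isoform accessions pass through).
#' @param cache_dir Directory for the JSON cache.
#' @param offline If `TRUE`, only the cache is consulted.
#' @return A [reference_sequence()].
#' @export
fetch_uniprot <- function(accession,
                          cache_dir = tools::R_user_dir("strucheck", "cache"),
                          offline = FALSE) {
  if (!is_uniprot_accession(accession)) {
    stop("'", accession, "' is not a syntactically valid UniProt accession",
         call. = FALSE)
  }
  cache_file <- file.path(cache_dir, paste0(accession, ".json"))
  if (file.exists(cache_file)) {
    rec <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    return(reference_sequence(rec$accession, rec$sequence))
  }
  if (offline) {
    stop("offline mode and no cached sequence for '", accession,
         "' in ", cache_dir, call. = FALSE)
  }
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  ok <- tryCatch(
    utils::download.file(url, tmp, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok || !file.exists(tmp) || file.size(tmp) == 0) {
    stop("could not retrieve UniProt entry '", accession,
         "': accession not found, obsolete, or network failure", call. = FALSE)
  }
  ref <- read_ref_fasta(tmp)
  ref$accession <- accession
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(accession = accession, sequence = ref$sequence,
         retrieved = format(Sys.Date())),
    cache_file, auto_unbox = TRUE
  )
  ref
}

#' Check the tool's input-size limits
#'
#' Custom PDB files are restricted to a maximum size of 5 MB, and
#' database-sourced entries containing more than 2,700 amino acids are not
#' supported (they are split across multiple model files upstream). Violations
#' are returned as blocking warnings; an empty vector means the inputs are
#' acceptable.
#'
#' @param structure_bytes Size of the structure file in bytes.
#' @param ref_length Length of the reference sequence.
#' @param source `"custom"` (uploaded file) or `"database"` (fetched entry).
#' @return Character vector of blocking warnings (possibly empty).
#' @export
validate_limits <- function(structure_bytes, ref_length,
                            source = c("custom", "database")) {
  source <- match.arg(source)
  warnings <- character(0)
  if (source == "custom" && structure_bytes > 5 * 1024^2) {
    warnings <- c(warnings, sprintf(
      "Custom PDB files are restricted to a maximum size of 5 MB (file is %.1f MB).",
      structure_bytes / 1024^2))
  }
  if (source == "database" && ref_length > 2700) {
    warnings <- c(warnings, sprintf(
      "Entries containing more than 2,700 amino acids are not supported (entry has %d).",
      ref_length))
  }
  warnings
}
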