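# From mapping rows to a renumbering plan, and serialisation of the outputs
# (TSV and JSON residue tables, FASTA alignment).

#' Build a renumbering plan from mapping rows
#'
#' Every aligned structure residue is assigned the UniProt identifier of the
#' position it aligns to; structure-only insertions are dropped (there is no
#' UniProt position to give them), preserving a one-to-one mapping with the
#' reference, and a warning summarising the removal is recorded. Missing
#' reference positions contribute nothing.
#'
#' @param rows Mapping rows from [classify()].
#' @return An object of class `renumber_plan`: `assignments` (named integer
#'   vector keyed by structure residue identifier, `NA` = drop), `dropped`
#'   (identifiers of removed insertions) and `warnings`.
#' @export
build_renumber_plan <- function(rows) {
  aligned <- rows$label %in% c("ID match", "ID mismatch")
  ins <- rows$label == "insertion"
  keys <- c(rows$structure_id[aligned], rows$structure_id[ins])
  if (anyDuplicated(keys)) {
    stop("internal consistency error: duplicate structure residue identifiers in mapping",
         call. = FALSE)
  }
  assignments <- c(
    stats::setNames(as.integer(rows$uniprot_id[aligned]), rows$structure_id[aligned]),
    stats::setNames(rep(NA_integer_, sum(ins)), rows$structure_id[ins])
  )
  dropped <- rows$structure_id[ins]
  warnings <- if (length(dropped)) {
    sprintf("%d inserted residue(s) not present in the reference sequence will be removed from the renumbered structure",
            length(dropped))
  } else character(0)
  structure(list(assignments = assignments, dropped = dropped,
                 warnings = warnings),
            class = "renumber_plan")
}

#' @export
print.renumber_plan <- function(x, ...) {
  cat(sprintf("Renumbering plan: %d residue(s) renumbered, %d dropped\n",
              sum(!is.na(x$assignments)), length(x$dropped)))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

TSV_HEADER <- paste("Alignment ID", "UniProt residue AA", "UniProt residue ID",
                    "Structure residue AA", "Structure residue ID", "label",
                    sep = "\t")

blank_na <- function(x) ifelse(is.na(x), "", as.character(x))

#' Serialise mapping rows as TSV
#'
#' Six tab-separated columns (alignment id, UniProt amino acid and
#' identifier, structure amino acid and identifier, label); absent sides are
#' blank cells. Newline-terminated, LF line endings.
#'
#' @param rows Mapping rows from [classify()].
#' @return TSV text.
#' @export
rows_to_tsv <- function(rows) {
  lines <- TSV_HEADER
  if (!is.null(rows) && nrow(rows)) {
    lines <- c(lines, paste(rows$alignment_id,
                            blank_na(rows$uniprot_aa),
                            blank_na(rows$uniprot_id),
                            blank_na(rows$structure_aa),
                            blank_na(rows$structure_id),
                            rows$label, sep = "\t"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialise mapping rows and summary as JSON
#'
#' One document with a `summary` object (all summary statistics, percent
#' identity rounded to 2 decimals, and both assessment messages verbatim)
#' and a `residues` array mirroring the TSV columns; absent sides are
#' `null`. Key order is fixed, so identical inputs give identical bytes.
#'
#' @param rows Mapping rows from [classify()].
#' @param stats The matching `summary_stats`; computed from `rows` if omitted.
#' @return JSON text.
#' @export
rows_to_json <- function(rows, stats = summarize_mapping(rows)) {
  doc <- list(
    summary = list(
      aln_length = stats$aln_length,
      identity_pct = round(stats$identity_pct, 2),
      identity_pct_aligned = round(stats$identity_pct_aligned, 2),
      n_gap_runs = stats$n_gap_runs,
      n_gap_columns = stats$n_gap_columns,
      n_variations = stats$n_variations,
      n_struct_residues = stats$n_struct_residues,
      n_id_match = stats$n_id_match,
      n_id_mismatch = stats$n_id_mismatch,
      n_missing = stats$n_missing,
      n_insertions = stats$n_insertions,
      sequence_assessment = stats$sequence_assessment,
      sequence_message = assess_sequence(stats)$message,
      id_assessment = stats$id_assessment,
      id_message = assess_identifiers(stats)$message
    ),
    residues = data.frame(
      alignment_id = rows$alignment_id,
      uniprot_aa = rows$uniprot_aa,
      uniprot_id = rows$uniprot_id,
      structure_aa = rows$structure_aa,
      structure_id = rows$structure_id,
      label = rows$label,
      stringsAsFactors = FALSE
    )
  )
  paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null", digits = NA,
                          pretty = TRUE), "\n")
}

#' Serialise an alignment as FASTA
#'
#' Two records, reference first, gap character `'-'`, wrapped at 60 columns;
#' both aligned strings have one character per alignment column.
#'
#' @param columns Alignment columns from [global_align()].
#' @param ref_id,query_id Record identifiers.
#' @return FASTA text.
#' @export
alignment_to_fasta <- function(columns, ref_id = "reference",
                               query_id = "structure") {
  if (is.null(columns) || nrow(columns) == 0) {
    stop("cannot serialise an empty alignment", call. = FALSE)
  }
  wrap <- function(s) {
    starts <- seq(1, nchar(s), by = 60)
    substring(s, starts, pmin(starts + 59, nchar(s)))
  }
  ref_s <- paste(columns$ref_aa, collapse = "")
  q_s <- paste(columns$query_aa, collapse = "")
  paste0(paste(c(paste0(">", ref_id), wrap(ref_s),
                 paste0(">", query_id), wrap(q_s)), collapse = "\n"), "\n")
}
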