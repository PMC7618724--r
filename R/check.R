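# The central check: structure + reference in, a classed result out, with
# the usual methods and file writers, plus the command-line flow.

resolve_reference <- function(reference, accession = NULL) {
  if (inherits(reference, "reference_sequence")) return(reference)
  if (length(reference) == 1 && grepl("^[A-Z]+$", reference) &&
      !file.exists(reference) && !startsWith(reference, ">")) {
    return(reference_sequence(accession %||% "REFERENCE", reference))
  }
  read_ref_fasta(reference, accession = accession)
}

resolve_structure <- function(structure, include_modified = FALSE) {
  if (inherits(structure, "pdb_structure")) return(structure)
  if (inherits(structure, "chain_sequence")) {
    # wrap a bare chain (e.g. from the fixture generator) as a model
    lines <- if (is.null(structure$atom_lines)) emit_pdb(structure) else NULL
    if (!is.null(lines)) return(read_pdb(lines, source_label = "<chain>"))
    stop("cannot wrap this chain_sequence; pass the pdb_structure instead",
         call. = FALSE)
  }
  read_pdb(structure, include_modified = include_modified)
}

#' Check a structure chain against a reference sequence
#'
#' Runs the whole consistency check: extracts the chain's amino-acid
#' sequence from the structure's ATOM records, aligns it globally to the
#' reference sequence, classifies every alignment column, computes summary
#' statistics and the two assessments (sequence-level and identifier-level),
#' and derives the renumbering plan that rewrites the chain in reference
#' (UniProt) coordinates.
#'
#' @param structure A PDB file path or text, a `pdb_structure`, or a
#'   `chain_sequence` (as produced by the fixture generator).
#' @param reference A [reference_sequence()], a FASTA path/text, or a bare
#'   amino-acid string.
#' @param chain Chain identifier (default `"A"`).
#' @param scoring A [scoring_scheme()].
#' @param include_modified Passed to [read_pdb()].
#' @return An object of class `strucheck`: `reference`, `model`, `chain`,
#'   `columns` (alignment), `mapping` (residue table), `stats`
#'   (`summary_stats`), `assessments` and `plan` (`renumber_plan`).
#' @examples
#' ref <- make_reference(60, seed = 1)
#' fx <- apply_edits(ref, edit_plan(numbering_offset = 10))
#' res <- strucheck(fx$chain, ref)
#' summary(res)
#' @export
strucheck <- function(structure, reference, chain = "A",
                      scoring = scoring_scheme(), include_modified = FALSE) {
  ref <- resolve_reference(reference)
  model <- resolve_structure(structure, include_modified = include_modified)
  ch <- extract_chain_sequence(model, chain)
  columns <- global_align(ref, ch, scoring)
  mapping <- classify(columns, ch)
  stats <- summarize_mapping(mapping)
  plan <- build_renumber_plan(mapping)
  structure(
    list(reference = ref, model = model, chain = ch, columns = columns,
         mapping = mapping, stats = stats,
         assessments = list(sequence = assess_sequence(stats),
                            identifiers = assess_identifiers(stats)),
         plan = plan, scoring = scoring),
    class = "strucheck"
  )
}

#' @export
print.strucheck <- function(x, ...) {
  cat(sprintf("Consistency check: %s (chain %s) vs %s\n",
              x$model$source_label, x$chain$chain_id, x$reference$accession))
  cat(sprintf("Reference length %d aa, structure %d residues\n\n",
              x$reference$length, x$stats$n_struct_residues))
  print(x$stats)
  for (w in x$plan$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
summary.strucheck <- function(object, ...) object$stats

#' @export
as.data.frame.strucheck <- function(x, ...) x$mapping

#' Plot the per-column labels of a consistency check
#'
#' A one-track overview of the alignment: each column coloured by its label
#' (identifier match/mismatch, missing, insertion), variations marked below.
#'
#' @param x A `strucheck` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.strucheck <- function(x, ...) {
  lab <- x$mapping$label
  pal <- c("ID match" = "#2b8cbe", "ID mismatch" = "#e34a33",
           missing = "#bdbdbd", insertion = "#31a354")
  n <- length(lab)
  graphics::plot(NULL, xlim = c(0, n), ylim = c(0, 2), xlab = "alignment column",
                 ylab = "", yaxt = "n", bty = "n",
                 main = sprintf("%s vs %s", x$chain$chain_id,
                                x$reference$accession), ...)
  graphics::rect(seq_len(n) - 1, 1, seq_len(n), 1.6, col = pal[lab],
                 border = NA)
  v <- which(x$mapping$variation)
  if (length(v)) graphics::points(v - 0.5, rep(0.7, length(v)), pch = 18,
                                  col = "#ff7f00")
  graphics::legend("bottom", horiz = TRUE, bty = "n", cex = 0.8,
                   fill = c(pal, "#ff7f00"),
                   legend = c(names(pal), "variation"))
  invisible(x)
}

#' Write all output files of a check
#'
#' Writes `mapping.tsv`, `mapping.json`, `alignment.fasta` and (when the
#' check was run on a structure model) `renumbered.pdb` into `dir`.
#'
#' @param x A `strucheck` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written (invisibly).
#' @export
write_outputs <- function(x, dir = ".") {
  stopifnot(inherits(x, "strucheck"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(tsv = file.path(dir, "mapping.tsv"),
             json = file.path(dir, "mapping.json"),
             fasta = file.path(dir, "alignment.fasta"),
             pdb = file.path(dir, "renumbered.pdb"))
  writeLines(sub("\n$", "", rows_to_tsv(x$mapping)), files["tsv"])
  writeLines(sub("\n$", "", rows_to_json(x$mapping, x$stats)), files["json"])
  writeLines(sub("\n$", "", alignment_to_fasta(
    x$columns, ref_id = x$reference$accession,
    query_id = paste0("structure_chain_", x$chain$chain_id))), files["fasta"])
  suppressWarnings(write_renumbered_pdb(
    x$model, x$chain$chain_id, x$plan,
    accession = x$reference$accession, path = files["pdb"]))
  invisible(files)
}

#' Exit status encoding the two assessments
#'
#' `0` when both the sequence and the identifiers match, `3` when the
#' sequences differ, `4` when only the identifiers differ. A pure function
#' of the summary statistics.
#'
#' @param x A `strucheck` object (or its `summary_stats`).
#' @return Integer status.
#' @export
exit_status <- function(x) {
  stats <- if (inherits(x, "strucheck")) x$stats else x
  if (stats$sequence_assessment != "SEQ_MATCH") return(3L)
  if (stats$id_assessment != "ID_MATCH") return(4L)
  0L
}

#' Run the full command-line flow
#'
#' Resolves the reference (local FASTA or UniProt fetch, honouring offline
#' mode), enforces the input limits before any computation, runs the check,
#' writes all output files, and logs the summary and the verbatim
#' assessment messages to stderr.
#'
#' @param structure Path to the structure file.
#' @param uniprot UniProt accession to fetch (ignored when `ref_fasta`
#'   is given).
#' @param ref_fasta Path to a local reference FASTA.
#' @param chain Chain identifier.
#' @param out_dir Output directory.
#' @param offline Never touch the network; requires `ref_fasta` or a cached
#'   accession.
#' @param scoring A [scoring_scheme()].
#' @param max_bytes Custom-file size limit in bytes.
#' @param source `"custom"` or `"database"` (decides which limits apply).
#' @param include_modified Passed to [read_pdb()].
#' @param cache_dir Cache directory for fetched sequences.
#' @param quiet Suppress the stderr log.
#' @return Invisibly, a list with `status` (see [exit_status()]), `files`
#'   and the `strucheck` result.
#' @export
run_check <- function(structure, uniprot = NULL, ref_fasta = NULL,
                      chain = "A", out_dir = ".", offline = FALSE,
                      scoring = scoring_scheme(), max_bytes = 5 * 1024^2,
                      source = c("custom", "database"),
                      include_modified = FALSE, cache_dir = NULL,
                      quiet = FALSE) {
  source <- match.arg(source)
  if (is.null(uniprot) && is.null(ref_fasta)) {
    stop("supply a UniProt accession or a reference FASTA file", call. = FALSE)
  }
  if (offline && is.null(ref_fasta) && !is.null(uniprot)) {
    cd <- cache_dir %||% tools::R_user_dir("strucheck", "cache")
    if (!file.exists(file.path(cd, paste0(uniprot, ".json")))) {
      stop("offline mode requires a reference FASTA or a cached accession",
           call. = FALSE)
    }
  }
  if (!file.exists(structure)) {
    stop("structure file not found: ", structure, call. = FALSE)
  }
  ref <- if (!is.null(ref_fasta)) read_ref_fasta(ref_fasta, accession = uniprot)
         else do.call(fetch_uniprot, c(list(uniprot, offline = offline),
                                       if (!is.null(cache_dir))
                                         list(cache_dir = cache_dir)))
  limit_warnings <- validate_limits(file.size(structure), ref$length, source)
  if (source == "custom" && file.size(structure) > max_bytes &&
      !length(limit_warnings)) {
    limit_warnings <- sprintf("structure file exceeds the %d-byte limit",
                              max_bytes)
  }
  if (length(limit_warnings)) {
    stop(paste(limit_warnings, collapse = "\n"), call. = FALSE)
  }
  res <- strucheck(structure, ref, chain = chain, scoring = scoring,
                   include_modified = include_modified)
  files <- write_outputs(res, out_dir)
  if (!quiet) {
    con <- textConnection("log_out", "w", local = TRUE)
    sink(con); print(res$stats); sink()
    close(con)
    message(paste(log_out, collapse = "\n"))
    for (w in res$plan$warnings) message("warning: ", w)
  }
  invisible(list(status = exit_status(res), files = files, result = res))
}
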