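# Global alignment of the reference (UniProt) sequence against the sequence
# read off a structure chain, plus per-column classification and summary
# statistics. The dynamic program is exact; ties between co-optimal
# alignments are broken deterministically at every traceback cell.

SEQ_MATCH_MSG <- "Your structure matches the UniProt sequence, safe to use!"
SEQ_DIFFER_MSG <- "Differences between the UniProt sequence and structure - use structure carefully"
ID_MATCH_MSG <- "Your structure matches the UniProt sequence identifiers, safe to map features!"
ID_DIFFER_MSG <- "Differences between the UniProt residue identifiers and structure residue identifiers - map UniProt annotations carefully"

#' Alignment scoring scheme
#'
#' Linear (per-column) gap scoring. The default -- match 1, mismatch 0,
#' gap 0 -- admits many co-optimal alignments, so the traceback preference
#' (`diagonal` > `up`, gap in the structure sequence, > `left`, gap in the
#' reference) is applied at every cell to make the result unique and
#' deterministic.
#'
#' @param match,mismatch,gap Column scores.
#' @param preference Traceback tie-break order; a permutation of
#'   `c("diagonal", "up", "left")`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = 0, gap = 0,
                           preference = c("diagonal", "up", "left")) {
  stopifnot(setequal(preference, c("diagonal", "up", "left")),
            length(preference) == 3)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 preference = preference),
            class = "scoring_scheme")
}

as_seq_chars <- function(x) {
  s <- if (inherits(x, "reference_sequence")) x$sequence
       else if (inherits(x, "chain_sequence")) x$sequence
       else as.character(x)
  strsplit(s, "")[[1]]
}

#' Needleman-Wunsch global alignment
#'
#' Aligns the full reference sequence to the full structure-derived sequence
#' under [scoring_scheme()], returning one row per alignment column. The
#' optimum is exact; among co-optimal alignments the one selected is fixed by
#' the traceback preference applied at every cell, so repeated runs on the
#' same inputs are identical.
#'
#' @param ref [reference_sequence()] or amino-acid string (rows of the DP
#'   matrix; gap here is a structure-only insertion).
#' @param query `chain_sequence` or amino-acid string.
#' @param scoring A [scoring_scheme()].
#' @return A data frame of alignment columns with `ref_pos` (1-based, `NA`
#'   at gaps), `query_index` (0-based residue order index, `NA` at gaps),
#'   `ref_aa` and `query_aa` (`"-"` at gaps), and the optimal score in
#'   `attr(, "score")`.
#' @export
global_align <- function(ref, query, scoring = scoring_scheme()) {
  a <- as_seq_chars(ref)
  b <- as_seq_chars(query)
  m <- length(a); n <- length(b)
  if (!m || !n) stop("cannot align an empty sequence", call. = FALSE)
  g <- scoring$gap
  tol <- 1e-9

  # H[i+1, j+1] = best score aligning a[1..i] with b[1..j]. Rows are filled
  # with a max-plus prefix scan so the left-dependency stays vectorised:
  # H[i+1, j+1] = max(diag, up, H[i+1, j] + g)
  #            = max_k<=j ( max(diag_k, up_k) + (j - k) g ).
  H <- matrix(0, m + 1L, n + 1L)
  H[1, ] <- (0:n) * g
  H[, 1] <- (0:m) * g
  jg <- (0:n) * g
  for (i in seq_len(m)) {
    sub <- ifelse(b == a[i], scoring$match, scoring$mismatch)
    cand <- pmax(H[i, 1:n] + sub, H[i, 2:(n + 1)] + g)
    C <- c(i * g, cand)
    H[i + 1, ] <- cummax(C - jg) + jg
  }

  # Traceback, preferring moves in scoring$preference order at each cell.
  cols_ref <- integer(m + n); cols_q <- integer(m + n)
  k <- 0L; i <- m; j <- n
  pref <- scoring$preference
  while (i > 0 || j > 0) {
    move <- NULL
    for (p in pref) {
      if (p == "diagonal" && i > 0 && j > 0) {
        s <- if (a[i] == b[j]) scoring$match else scoring$mismatch
        if (abs(H[i + 1, j + 1] - (H[i, j] + s)) < tol) { move <- "diagonal"; break }
      } else if (p == "up" && i > 0) {
        if (abs(H[i + 1, j + 1] - (H[i, j + 1] + g)) < tol) { move <- "up"; break }
      } else if (p == "left" && j > 0) {
        if (abs(H[i + 1, j + 1] - (H[i + 1, j] + g)) < tol) { move <- "left"; break }
      }
    }
    k <- k + 1L
    if (move == "diagonal") {
      cols_ref[k] <- i; cols_q[k] <- j; i <- i - 1L; j <- j - 1L
    } else if (move == "up") {
      cols_ref[k] <- i; cols_q[k] <- NA_integer_; i <- i - 1L
    } else {
      cols_ref[k] <- NA_integer_; cols_q[k] <- j; j <- j - 1L
    }
  }
  rp <- rev(cols_ref[1:k]); qi <- rev(cols_q[1:k])
  out <- data.frame(
    ref_pos = rp,
    query_index = qi - 1L,
    ref_aa = ifelse(is.na(rp), "-", a[ifelse(is.na(rp), 1L, rp)]),
    query_aa = ifelse(is.na(qi), "-", b[ifelse(is.na(qi), 1L, qi)]),
    stringsAsFactors = FALSE
  )
  attr(out, "score") <- H[m + 1, n + 1]
  out
}

#' Classify alignment columns into the residue mapping table
#'
#' Produces one mapping row per alignment column: the UniProt amino acid and
#' identifier, the structure amino acid and author identifier, a label
#' (`ID match` when the author identifier equals the UniProt position and
#' carries no insertion code; `ID mismatch` otherwise for aligned pairs;
#' `missing` for reference-only columns; `insertion` for structure-only
#' columns) and a variation flag for aligned pairs whose amino acids differ
#' (an `'X'` residue never counts as identical).
#'
#' @param columns Alignment columns from [global_align()].
#' @param query The `chain_sequence` the alignment was computed against
#'   (source of author residue identifiers).
#' @return A data frame of mapping rows: `alignment_id`, `uniprot_aa`,
#'   `uniprot_id`, `structure_aa`, `structure_id`, `label`, `variation`.
#' @export
classify <- function(columns, query) {
  stopifnot(inherits(query, "chain_sequence"))
  res <- query$residues
  qi <- columns$query_index
  res_seq <- ifelse(is.na(qi), NA_integer_, res$res_seq[qi + 1L])
  icode <- ifelse(is.na(qi), NA_character_, res$icode[qi + 1L])
  has_ref <- !is.na(columns$ref_pos)
  has_q <- !is.na(qi)
  label <- ifelse(!has_q, "missing",
           ifelse(!has_ref, "insertion",
           ifelse(icode == "" & res_seq == columns$ref_pos,
                  "ID match", "ID mismatch")))
  identical_aa <- has_ref & has_q & columns$ref_aa == columns$query_aa &
    columns$ref_aa != "X"
  data.frame(
    alignment_id = seq_len(nrow(columns)),
    uniprot_aa = ifelse(has_ref, columns$ref_aa, NA_character_),
    uniprot_id = columns$ref_pos,
    structure_aa = ifelse(has_q, columns$query_aa, NA_character_),
    structure_id = ifelse(has_q, structure_id(res_seq, icode), NA_character_),
    label = label,
    variation = has_ref & has_q & !identical_aa,
    stringsAsFactors = FALSE
  )
}

#' Summary statistics of a residue mapping
#'
#' Counts over the mapping rows: alignment length, percent identity (equal
#' aligned amino acids over all alignment columns, gaps included; the
#' aligned-pairs-only percentage is kept as a secondary field), gap runs and
#' gapped columns, variations, and the identifier-agreement counts, plus the
#' two assessment outcomes.
#'
#' @param rows Mapping rows from [classify()].
#' @return An object of class `summary_stats`.
#' @export
summarize_mapping <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) {
    stop("cannot summarise an empty mapping", call. = FALSE)
  }
  has_ref <- !is.na(rows$uniprot_aa)
  has_q <- !is.na(rows$structure_aa)
  identical_aa <- has_ref & has_q & !rows$variation
  gap_col <- !(has_ref & has_q)
  runs <- rle(gap_col)
  stats <- list(
    aln_length = nrow(rows),
    identity_pct = 100 * sum(identical_aa) / nrow(rows),
    identity_pct_aligned = if (any(has_ref & has_q))
      100 * sum(identical_aa) / sum(has_ref & has_q) else NA_real_,
    n_gap_runs = sum(runs$values),
    n_gap_columns = sum(gap_col),
    n_variations = sum(rows$variation),
    n_struct_residues = sum(has_q),
    n_id_match = sum(rows$label == "ID match"),
    n_id_mismatch = sum(rows$label == "ID mismatch"),
    n_missing = sum(rows$label == "missing"),
    n_insertions = sum(rows$label == "insertion")
  )
  stats$sequence_assessment <-
    if (sum(identical_aa) == stats$aln_length && stats$n_gap_columns == 0)
      "SEQ_MATCH" else "SEQ_DIFFER"
  stats$id_assessment <-
    if (stats$n_id_mismatch == 0 && stats$n_insertions == 0)
      "ID_MATCH" else "ID_DIFFER"
  structure(stats, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Alignment length:        %d\n", x$aln_length))
  cat(sprintf("Sequence identity:       %.2f%% (%.2f%% of aligned pairs)\n",
              x$identity_pct, x$identity_pct_aligned))
  cat(sprintf("Gaps:                    %d run(s), %d column(s)\n",
              x$n_gap_runs, x$n_gap_columns))
  cat(sprintf("Variations:              %d\n", x$n_variations))
  cat(sprintf("Structure residues:      %d\n", x$n_struct_residues))
  cat(sprintf("  identifier match:      %d\n", x$n_id_match))
  cat(sprintf("  identifier mismatch:   %d\n", x$n_id_mismatch))
  cat(sprintf("  insertions:            %d\n", x$n_insertions))
  cat(sprintf("Missing from structure:  %d\n", x$n_missing))
  cat(assess_sequence(x)$message, "\n")
  cat(assess_identifiers(x)$message, "\n")
  invisible(x)
}

#' Sequence-level assessment
#'
#' The structure is declared safe to use only when the sequence identity is
#' 100% and the alignment has no gapped columns (full coverage); otherwise
#' the cautionary message is returned.
#'
#' @param stats A `summary_stats` object.
#' @return List with `status` (`"SEQ_MATCH"`/`"SEQ_DIFFER"`) and `message`.
#' @export
assess_sequence <- function(stats) {
  if (stats$sequence_assessment == "SEQ_MATCH") {
    list(status = "SEQ_MATCH", message = SEQ_MATCH_MSG)
  } else {
    list(status = "SEQ_DIFFER", message = SEQ_DIFFER_MSG)
  }
}

#' Identifier-level assessment
#'
#' Identifiers are declared safe for feature mapping when no aligned residue
#' mismatches its UniProt position and the structure has no insertions;
#' missing residues are allowed (annotations simply have no residue to land
#' on there).
#'
#' @param stats A `summary_stats` object.
#' @return List with `status` (`"ID_MATCH"`/`"ID_DIFFER"`) and `message`.
#' @export
assess_identifiers <- function(stats) {
  if (stats$id_assessment == "ID_MATCH") {
    list(status = "ID_MATCH", message = ID_MATCH_MSG)
  } else {
    list(status = "ID_DIFFER", message = ID_DIFFER_MSG)
  }
}
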