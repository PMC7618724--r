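# Deterministic synthetic fixtures: a random reference sequence and a
# structure chain derived from it by terminal truncations, internal
# deletions, insertions, substitutions and numbering changes, with the
# by-construction mapping rows kept as ground truth. Every other module is
# testable against these without any download.

#' Generate a random reference sequence
#'
#' Uniform draw over the 20 standard amino acids from a seeded generator;
#' the same `(length, seed)` always yields the same sequence.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @param accession Label for the synthetic reference.
#' @return A [reference_sequence()].
#' @export
make_reference <- function(length, seed,
                           accession = sprintf("SYNREF-%d-%d", length, seed)) {
  if (length < 1) stop("reference length must be >= 1", call. = FALSE)
  seq <- with_seed(seed, paste(sample(AA20, length, replace = TRUE), collapse = ""))
  reference_sequence(accession, seq)
}

#' Construct an edit plan
#'
#' Describes how a structure chain is derived from a reference sequence.
#' Edits must be pairwise disjoint and separated by at least two unedited
#' positions, and must satisfy anchor conditions (checked against the
#' sequence in [apply_edits()]) under which the default scoring admits a
#' unique optimal alignment, so the by-construction labels are exactly what
#' the pipeline must recover.
#'
#' @param n_term_trunc,c_term_trunc Residues removed from the termini.
#' @param internal_deletions Data frame (or list coercible to one) with
#'   columns `start`, `length`, in reference coordinates.
#' @param substitutions Data frame with columns `pos`, `aa`.
#' @param insertions Data frame with columns `after` (reference position,
#'   0 allowed for a leading insertion) and `seq` (inserted letters).
#' @param numbering_offset Integer added to every emitted residue number.
#' @param icode_positions Reference positions whose structure residue gets
#'   insertion code `"A"` (forcing an identifier mismatch).
#' @param renumber_from If not `NULL`, emitted residue numbers are instead
#'   `renumber_from + order index` (sequential numbering, as in model files
#'   numbered from 1), overriding `numbering_offset`.
#' @return An object of class `edit_plan`.
#' @export
edit_plan <- function(n_term_trunc = 0L, c_term_trunc = 0L,
                      internal_deletions = NULL, substitutions = NULL,
                      insertions = NULL, numbering_offset = 0L,
                      icode_positions = integer(0), renumber_from = NULL) {
  norm_df <- function(x, cols) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
      return(stats::setNames(
        data.frame(integer(0), if ("aa" %in% cols || "seq" %in% cols)
          character(0) else integer(0)), cols))
    }
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot(all(cols %in% names(x)))
    x[cols]
  }
  structure(list(
    n_term_trunc = as.integer(n_term_trunc),
    c_term_trunc = as.integer(c_term_trunc),
    internal_deletions = norm_df(internal_deletions, c("start", "length")),
    substitutions = norm_df(substitutions, c("pos", "aa")),
    insertions = norm_df(insertions, c("after", "seq")),
    numbering_offset = as.integer(numbering_offset),
    icode_positions = as.integer(icode_positions),
    renumber_from = if (is.null(renumber_from)) NULL else as.integer(renumber_from)
  ), class = "edit_plan")
}

# Edit intervals in reference coordinates; insertions as zero-width points.
plan_intervals <- function(plan, L) {
  iv <- list()
  if (plan$n_term_trunc > 0) iv[[length(iv) + 1]] <- c(1, plan$n_term_trunc)
  if (plan$c_term_trunc > 0) iv[[length(iv) + 1]] <- c(L - plan$c_term_trunc + 1, L)
  for (k in seq_len(nrow(plan$internal_deletions))) {
    d <- plan$internal_deletions[k, ]
    iv[[length(iv) + 1]] <- c(d$start, d$start + d$length - 1)
  }
  for (p in plan$substitutions$pos) iv[[length(iv) + 1]] <- c(p, p)
  for (p in plan$insertions$after) iv[[length(iv) + 1]] <- c(p + 0.4, p + 0.6)
  iv
}

validate_plan <- function(plan, ref) {
  L <- ref$length
  chars <- strsplit(ref$sequence, "")[[1]]
  dels <- plan$internal_deletions
  if (plan$n_term_trunc < 0 || plan$c_term_trunc < 0 ||
      plan$n_term_trunc + plan$c_term_trunc >= L) {
    stop("terminal truncations out of range", call. = FALSE)
  }
  if (nrow(dels) && (any(dels$start < 1) || any(dels$length < 1) ||
                     any(dels$start + dels$length - 1 > L))) {
    stop("internal deletion out of range", call. = FALSE)
  }
  if (any(plan$substitutions$pos < 1) || any(plan$substitutions$pos > L)) {
    stop("substitution position out of range", call. = FALSE)
  }
  if (any(plan$insertions$after < 0) || any(plan$insertions$after > L)) {
    stop("insertion position out of range", call. = FALSE)
  }
  iv <- plan_intervals(plan, L)
  if (length(iv) > 1) {
    ord <- order(vapply(iv, `[`, numeric(1), 1))
    iv <- iv[ord]
    for (k in seq_len(length(iv) - 1)) {
      lo <- ceiling(iv[[k]][2] + 1e-9)
      hi <- floor(iv[[k + 1]][1] - 1e-9)
      if (iv[[k + 1]][1] <= iv[[k]][2]) {
        stop("overlapping edits in plan", call. = FALSE)
      }
      if (hi - lo + 1 < 2) {
        stop("edits must be separated by at least 2 unedited positions",
             call. = FALSE)
      }
    }
  }
  # Anchor conditions: forbid equal-score leftward slides of gap blocks and
  # no-op substitutions, so the optimal alignment (and hence the ground
  # truth) is unique under the default scoring.
  del_blocks <- dels
  if (plan$c_term_trunc > 0) {
    del_blocks <- rbind(del_blocks,
                        data.frame(start = L - plan$c_term_trunc + 1,
                                   length = plan$c_term_trunc))
  }
  for (k in seq_len(nrow(del_blocks))) {
    d <- del_blocks[k, ]; e <- d$start + d$length - 1
    if (d$start > 1 && chars[d$start - 1] %in% chars[d$start:e]) {
      stop("ambiguous edit plan: deletion block at ", d$start,
           " admits a co-optimal gap placement (left-flank residue recurs ",
           "inside the block)", call. = FALSE)
    }
  }
  # Residue types occurring in any deleted block: a substituted or inserted
  # residue of such a type could pair into the block at a strictly better
  # score (free gaps make this scoring behave like a longest common
  # subsequence), so the constructed labels would not be the optimum.
  block_chars <- unique(unlist(lapply(seq_len(nrow(del_blocks)), function(k) {
    d <- del_blocks[k, ]; chars[d$start:(d$start + d$length - 1)]
  })))
  if (plan$n_term_trunc > 0) {
    block_chars <- unique(c(block_chars, chars[1:plan$n_term_trunc]))
  }
  for (k in seq_len(nrow(plan$insertions))) {
    ins <- plan$insertions[k, ]
    s <- strsplit(toupper(ins$seq), "")[[1]]
    if (!length(s) || !all(s %in% AA20)) {
      stop("inserted sequence must be standard amino acids", call. = FALSE)
    }
    if (ins$after >= 1 && chars[ins$after] %in% s) {
      stop("ambiguous edit plan: insertion after ", ins$after,
           " admits a co-optimal gap placement (flanking residue recurs ",
           "in the inserted segment)", call. = FALSE)
    }
    if (any(s %in% block_chars)) {
      stop("ambiguous edit plan: inserted residue type also occurs in a ",
           "deleted block", call. = FALSE)
    }
  }
  for (k in seq_len(nrow(plan$substitutions))) {
    sb <- plan$substitutions[k, ]
    if (!toupper(sb$aa) %in% AA20) {
      stop("substitution must be a standard amino acid", call. = FALSE)
    }
    if (toupper(sb$aa) == chars[sb$pos]) {
      stop("substitution at ", sb$pos, " does not change the residue",
           call. = FALSE)
    }
    if (toupper(sb$aa) %in% block_chars) {
      stop("ambiguous edit plan: substituted residue type also occurs in a ",
           "deleted block", call. = FALSE)
    }
  }
  # A deletion block close to an insertion lets residues in the short
  # unedited bridge between them re-pair through the block at equal score
  # (the block frees reference slots, the insertion supplies query
  # residues), so within a 10-residue bridge the residue types of block,
  # bridge and inserted segment must be mutually disjoint.
  for (k in seq_len(nrow(del_blocks))) {
    d <- del_blocks[k, ]; e <- d$start + d$length - 1
    btypes <- unique(chars[d$start:e])
    for (j in seq_len(nrow(plan$insertions))) {
      ins <- plan$insertions[j, ]
      s <- unique(strsplit(toupper(ins$seq), "")[[1]])
      bridge <- if (ins$after >= e) seq2(e + 1, ins$after)
                else seq2(ins$after + 1, d$start - 1)
      bridge <- bridge[bridge >= 1 & bridge <= L]
      if (length(bridge) > 10) next
      btyp_bridge <- unique(chars[bridge])
      if (any(btypes %in% c(btyp_bridge, s)) ||
          any(s %in% c(btyp_bridge, btypes))) {
        stop("ambiguous edit plan: deletion block at ", d$start,
             " and insertion after ", ins$after, " share residue types ",
             "with each other or their bridge", call. = FALSE)
      }
    }
  }
  if (any(plan$icode_positions < 1) || any(plan$icode_positions > L)) {
    stop("icode position out of range", call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply an edit plan to a reference sequence
#'
#' Derives the structure chain the plan describes and the by-construction
#' ground-truth mapping rows (the same shape as [classify()] output):
#' deleted positions are `missing`, inserted residues `insertion`, aligned
#' residues `ID match` or `ID mismatch` according to the emitted numbering,
#' and substituted positions carry the variation flag.
#'
#' @param ref A [reference_sequence()].
#' @param plan An [edit_plan()]; validated against `ref` (overlapping edits
#'   or ambiguous plans are rejected).
#' @param chain_id Chain identifier for the derived chain.
#' @return List with `chain` (a `chain_sequence`), `truth` (mapping rows),
#'   `ref` and `plan`.
#' @export
apply_edits <- function(ref, plan, chain_id = "A") {
  stopifnot(inherits(ref, "reference_sequence"), inherits(plan, "edit_plan"))
  validate_plan(plan, ref)
  L <- ref$length
  chars <- strsplit(ref$sequence, "")[[1]]

  deleted <- logical(L)
  if (plan$n_term_trunc > 0) deleted[1:plan$n_term_trunc] <- TRUE
  if (plan$c_term_trunc > 0) deleted[(L - plan$c_term_trunc + 1):L] <- TRUE
  for (k in seq_len(nrow(plan$internal_deletions))) {
    d <- plan$internal_deletions[k, ]
    deleted[d$start:(d$start + d$length - 1)] <- TRUE
  }
  sub_at <- stats::setNames(toupper(plan$substitutions$aa), plan$substitutions$pos)
  ins_at <- stats::setNames(toupper(plan$insertions$seq), plan$insertions$after)

  n_rows <- 0L
  rows <- vector("list", L + sum(nchar(plan$insertions$seq)) + 2L)
  res_seq <- integer(0); icode <- character(0); one <- character(0)
  k <- 0L  # structure order index (0-based is k-1 after increment)

  add_row <- function(uaa, uid, saa, sid, label, var) {
    n_rows <<- n_rows + 1L
    rows[[n_rows]] <<- data.frame(
      alignment_id = n_rows, uniprot_aa = uaa, uniprot_id = uid,
      structure_aa = saa, structure_id = sid, label = label,
      variation = var, stringsAsFactors = FALSE)
  }
  emit_residue <- function(aa, num, ic) {
    k <<- k + 1L
    res_seq[k] <<- num; icode[k] <<- ic; one[k] <<- aa
  }
  number_for <- function(order_index0, pos) {
    if (!is.null(plan$renumber_from)) plan$renumber_from + order_index0
    else pos + plan$numbering_offset
  }

  handle_insertions <- function(pos) {
    s <- unname(ins_at[as.character(pos)])
    if (is.na(s)) return(invisible())
    ins_chars <- strsplit(s, "")[[1]]
    for (j in seq_along(ins_chars)) {
      if (!is.null(plan$renumber_from)) {
        num <- plan$renumber_from + k; ic <- ""
      } else {
        # inserted residues share the flanking number, distinguished by
        # insertion codes, as author-numbered files do
        num <- max(pos, 1L) + plan$numbering_offset
        ic <- LETTERS[j + as.integer(pos %in% plan$icode_positions)]
      }
      emit_residue(ins_chars[j], num, ic)
      add_row(NA_character_, NA_integer_, ins_chars[j],
              structure_id(num, ic), "insertion", FALSE)
    }
  }

  handle_insertions(0L)
  for (pos in seq_len(L)) {
    if (deleted[pos]) {
      add_row(chars[pos], pos, NA_character_, NA_character_, "missing", FALSE)
    } else {
      aa <- unname(sub_at[as.character(pos)])
      is_sub <- !is.na(aa)
      if (!is_sub) aa <- chars[pos]
      ic <- if (is.null(plan$renumber_from) && pos %in% plan$icode_positions)
        "A" else ""
      num <- number_for(k, pos)
      emit_residue(aa, num, ic)
      label <- if (ic == "" && num == pos) "ID match" else "ID mismatch"
      add_row(chars[pos], pos, aa, structure_id(num, ic), label, is_sub)
    }
    handle_insertions(pos)
  }

  truth <- do.call(rbind, rows[seq_len(n_rows)])
  residues <- data.frame(
    order_index = seq_len(k) - 1L,
    res_seq = res_seq, icode = icode,
    res_name = unname(AA_ONE_TO_THREE[one]),
    one_letter = one, stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(res_seq, icode))) {
    stop("edit plan produces duplicate residue identifiers", call. = FALSE)
  }
  chain <- structure(
    list(chain_id = chain_id, residues = residues,
         sequence = paste(one, collapse = ""), atom_lines = NULL),
    class = "chain_sequence"
  )
  list(chain = chain, truth = truth, ref = ref, plan = plan)
}

#' Emit a minimal CA-only PDB file for a chain
#'
#' One CA ATOM line per residue with correct fixed-column formatting
#' (residue number in columns 23-26, insertion code in column 27) and
#' placeholder coordinates, terminated by TER and END. Reading the output
#' back with [read_pdb()] reproduces the chain exactly.
#'
#' @param chain A `chain_sequence`.
#' @return PDB text as a character vector of lines.
#' @export
emit_pdb <- function(chain) {
  stopifnot(inherits(chain, "chain_sequence"))
  res <- chain$residues
  if (!nrow(res)) stop("cannot emit an empty chain", call. = FALSE)
  if (min(res$res_seq) < -999 || max(res$res_seq) > 9999) {
    stop("residue number outside -999..9999 cannot be formatted", call. = FALSE)
  }
  n <- nrow(res)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), res$res_name, chain$chain_id, res$res_seq,
    ifelse(res$icode == "", " ", res$icode),
    3.8 * (seq_len(n) - 1), 0, 0, 1, 0
  )
  c(lines, "TER", "END")
}

#' Generate a random valid edit plan
#'
#' Samples truncations, internal deletions, substitutions, insertions and a
#' numbering change for the given reference, resampling deterministically
#' until the plan passes [edit_plan()] validity (disjoint, spaced, anchored)
#' -- so the ground truth of [apply_edits()] is always uniquely recoverable.
#'
#' @param ref A [reference_sequence()] (length >= 40 recommended).
#' @param seed Integer seed.
#' @return An [edit_plan()].
#' @export
random_edit_plan <- function(ref, seed) {
  L <- ref$length
  chars <- strsplit(ref$sequence, "")[[1]]
  with_seed(seed, {
    for (attempt in 1:200) {
      plan <- tryCatch({
        n_term <- sample(0:3, 1, prob = c(0.7, 0.1, 0.1, 0.1))
        c_term <- sample(0:3, 1, prob = c(0.7, 0.1, 0.1, 0.1))
        n_del <- sample(0:2, 1)
        dels <- if (n_del) data.frame(
          start = sort(sample(5:(L - 10), n_del)),
          length = sample(1:8, n_del, replace = TRUE)) else NULL
        deleted_pos <- c(seq_len(n_term), if (c_term) (L - c_term + 1):L,
                         unlist(lapply(seq_len(n_del), function(k)
                           dels$start[k]:(dels$start[k] + dels$length[k] - 1))))
        free <- setdiff(AA20, chars[deleted_pos])
        n_sub <- sample(0:3, 1)
        subs <- if (n_sub) {
          pos <- sort(sample(seq_len(L), n_sub))
          data.frame(pos = pos,
                     aa = vapply(pos, function(p)
                       sample(setdiff(free, chars[p]), 1), character(1)))
        } else NULL
        n_ins <- sample(0:2, 1)
        ins <- if (n_ins) data.frame(
          after = sort(sample(0:L, n_ins)),
          seq = vapply(seq_len(n_ins), function(i)
            paste(sample(free, sample(1:4, 1), replace = TRUE), collapse = ""),
            character(1))) else NULL
        numbering <- sample(c("match", "offset", "sequential"), 1,
                            prob = c(0.4, 0.4, 0.2))
        plan <- edit_plan(
          n_term_trunc = n_term, c_term_trunc = c_term,
          internal_deletions = dels, substitutions = subs, insertions = ins,
          numbering_offset = if (numbering == "offset")
            sample(c(-50:-1, 1:96), 1) else 0L,
          icode_positions = if (numbering != "sequential" && sample(4, 1) == 1)
            sample(setdiff(seq_len(L), c(ins$after, ins$after + 1L)), 1)
          else integer(0),
          renumber_from = if (numbering == "sequential") 1L else NULL
        )
        validate_plan(plan, ref)
        plan
      }, error = function(e) NULL)
      if (!is.null(plan)) return(plan)
    }
    stop("could not sample a valid edit plan for this reference", call. = FALSE)
  })
}

#' Synthetic twin of an outdated-model scenario
#'
#' Builds a 478-residue reference and a derived chain with a 96-residue
#' internal deletion spanning positions 11..106, two substitutions near the
#' N-terminus, and sequential numbering starting at 1 -- the situation of a
#' model built from a superseded sequence record: the chain has 382
#' residues and reference position 107 carries structure number 11. The
#' reference is drawn from the seeded generator and minimally adjusted so
#' the deleted block satisfies the unique-alignment anchor condition.
#'
#' @param seed Integer seed.
#' @return As [apply_edits()], i.e. `chain`, `truth`, `ref`, `plan`.
#' @export
twin_fixture <- function(seed) {
  # Residue types are partitioned so the deleted block shares no type with
  # the N-terminal segment or the substituted residues: this makes the
  # constructed alignment the unique optimum (no residue outside the block
  # can pair into it), so the whole mapping is recoverable exactly.
  head_alph <- AA20[1:12]
  block_alph <- AA20[13:20]
  chars <- with_seed(seed, c(
    sample(head_alph, 10, replace = TRUE),   # positions 1..10
    sample(block_alph, 96, replace = TRUE),  # 11..106, the deleted block
    sample(AA20, 372, replace = TRUE)        # 107..478
  ))
  ref <- reference_sequence(sprintf("SYNTWIN-%d", seed),
                            paste(chars, collapse = ""))
  subs <- data.frame(
    pos = c(2L, 5L),
    aa = with_seed(seed + 1L, vapply(c(2L, 5L), function(p)
      sample(setdiff(head_alph, chars[p]), 1), character(1))))
  plan <- edit_plan(internal_deletions = data.frame(start = 11L, length = 96L),
                    substitutions = subs, renumber_from = 1L)
  apply_edits(ref, plan)
}
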