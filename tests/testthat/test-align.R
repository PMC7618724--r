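test_that("identical sequences align with no gaps and full score", {
  cols <- global_align("ACDE", "ACDE")
  expect_equal(nrow(cols), 4)
  expect_equal(cols$ref_pos, 1:4)
  expect_equal(cols$query_index, 0:3)
  expect_false(any(cols$ref_aa == "-" | cols$query_aa == "-"))
  expect_equal(attr(cols, "score"), 4)
})

test_that("an internal deletion leaves reference-only columns", {
  # expected alignment frozen from the enumeration oracle:
  # AA CC D- E- FF GG, score 4
  cols <- global_align("ACDEFG", "ACFG")
  expect_equal(attr(cols, "score"), 4)
  expect_equal(aln_signature(cols), "AA CC D- E- FF GG")
  or <- oracle_align("ACDEFG", "ACFG")
  expect_equal(attr(cols, "score"), or$score)
  expect_equal(aln_signature(cols),
               aln_signature(oracle_columns(or$moves, "ACDEFG", "ACFG")))
})

test_that("a tied single-residue pair prefers the diagonal (mismatch) move", {
  cols <- global_align("A", "G")
  expect_equal(nrow(cols), 1)
  expect_equal(cols$ref_aa, "A")
  expect_equal(cols$query_aa, "G")
  expect_error(global_align("", "A"), "empty")
})

test_that("alignment equals exhaustive enumeration on random short pairs", {
  set.seed(202)
  for (k in 1:200) {
    s1 <- paste(sample(c("A", "C", "D", "E"), sample(1:8, 1), replace = TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "D", "E"), sample(1:8, 1), replace = TRUE),
                collapse = "")
    or <- oracle_align(s1, s2)
    im <- global_align(s1, s2)
    expect_equal(attr(im, "score"), or$score)
    expect_equal(aln_signature(im),
                 aln_signature(oracle_columns(or$moves, s1, s2)))
  }
})

test_that("labels follow the author numbering, not just the sequence", {
  perfect <- perfect_fixture(30, 4)
  rows <- strucheck(perfect$chain, perfect$ref)$mapping
  expect_true(all(rows$label == "ID match"))

  off <- apply_edits(make_reference(30, 4), edit_plan(numbering_offset = 10L))
  rows_off <- strucheck(off$chain, off$ref)$mapping
  expect_true(all(rows_off$label == "ID mismatch"))
  expect_false(any(rows_off$variation))

  ic <- apply_edits(make_reference(30, 4), edit_plan(icode_positions = 12L))
  rows_ic <- strucheck(ic$chain, ic$ref)$mapping
  expect_equal(rows_ic$label[12], "ID mismatch")
  expect_equal(rows_ic$structure_id[12], "12A")
  expect_equal(sum(rows_ic$label == "ID mismatch"), 1)
})

test_that("X never counts as identity and always flags a variation", {
  lines <- pdb_text(atom_line(1, "MET", "A", 1),
                    atom_line(2, "FOO", "A", 2),
                    atom_line(3, "VAL", "A", 3))
  res <- strucheck(lines, reference_sequence("T1", "MKV"))
  expect_true(res$mapping$variation[2])
  expect_lt(res$stats$identity_pct, 100)
  # X aligned to X still never counts as identical
  res2 <- strucheck(lines, reference_sequence("T2", "MXV"))
  expect_true(res2$mapping$variation[2])
  expect_equal(res2$stats$identity_pct, 100 * 2 / 3)
})

test_that("summary counts are exact on a hand-countable fixture", {
  # 20-residue reference, one 5-residue deletion, one substitution:
  # 20 columns, 14 identical -> 70% identity
  ref <- make_reference(20, 1)
  fx <- apply_edits(ref, edit_plan(
    internal_deletions = data.frame(start = 8, length = 5),
    substitutions = data.frame(pos = 3, aa = "C")))
  st <- strucheck(fx$chain, ref)$stats
  expect_equal(st$aln_length, 20)
  expect_equal(st$n_missing, 5)
  expect_equal(st$n_variations, 1)
  expect_equal(st$identity_pct, 70)
  expect_equal(st$n_gap_runs, 1)
  expect_equal(st$n_struct_residues, 15)
})

test_that("identical sequences summarise to a perfect report", {
  fx <- perfect_fixture(25, 9)
  st <- strucheck(fx$chain, fx$ref)$stats
  expect_equal(st$identity_pct, 100)
  expect_equal(st$n_gap_runs, 0)
  expect_equal(st$n_variations, 0)
  expect_error(summarize_mapping(NULL), "empty")
})

test_that("assessment messages are exact and coverage-aware", {
  perfect <- perfect_fixture(30, 11)
  st <- strucheck(perfect$chain, perfect$ref)$stats
  expect_equal(assess_sequence(st)$message,
               "Your structure matches the UniProt sequence, safe to use!")
  expect_equal(assess_identifiers(st)$message,
               "Your structure matches the UniProt sequence identifiers, safe to map features!")

  # a pure fragment: every aligned pair identical, but coverage incomplete
  frag <- apply_edits(make_reference(40, 12), edit_plan(n_term_trunc = 6L))
  st_frag <- strucheck(frag$chain, frag$ref)$stats
  expect_equal(st_frag$identity_pct_aligned, 100)
  expect_equal(assess_sequence(st_frag)$status, "SEQ_DIFFER")
  expect_equal(assess_sequence(st_frag)$message,
               "Differences between the UniProt sequence and structure - use structure carefully")
  # missing residues alone do not break the identifier assessment
  expect_equal(assess_identifiers(st_frag)$status, "ID_MATCH")

  off <- apply_edits(make_reference(30, 4), edit_plan(numbering_offset = 1L))
  st_off <- strucheck(off$chain, off$ref)$stats
  expect_equal(assess_identifiers(st_off)$status, "ID_DIFFER")
  expect_equal(assess_identifiers(st_off)$message,
               "Differences between the UniProt residue identifiers and structure residue identifiers - map UniProt annotations carefully")
})

test_that("swapping the sequences mirrors missing and insertion columns", {
  # stated for inputs whose optimal alignment is unique (fixture pairs);
  # under the degenerate default scoring, unrelated random strings have
  # co-optimal alignments and the tie-break is direction-dependent
  for (seed in c(2, 13, 41, 88)) {
    ref <- make_reference(90, seed)
    fx <- apply_edits(ref, random_edit_plan(ref, seed + 9000))
    ab <- global_align(ref$sequence, fx$chain$sequence)
    ba <- global_align(fx$chain$sequence, ref$sequence)
    expect_equal(sum(ab$query_aa == "-"), sum(is.na(ba$ref_pos)))
    expect_equal(sum(is.na(ab$ref_pos)), sum(ba$query_aa == "-"))
    expect_gt(sum(ab$query_aa == "-") + sum(is.na(ab$ref_pos)), 0)
  }
})

test_that("extra edits never decrease the matching discrepancy counts", {
  found <- FALSE
  for (seed in 1:20) {
    ref <- make_reference(100, seed)
    chars <- strsplit(ref$sequence, "")[[1]]
    free <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], chars[30:34])
    base <- try(apply_edits(ref, edit_plan(
      internal_deletions = data.frame(start = 30, length = 5))), silent = TRUE)
    if (inherits(base, "try-error")) next
    sub_aa <- setdiff(free, chars[70])[1]
    plus_sub <- try(apply_edits(ref, edit_plan(
      internal_deletions = data.frame(start = 30, length = 5),
      substitutions = data.frame(pos = 70, aa = sub_aa))), silent = TRUE)
    if (inherits(plus_sub, "try-error")) next
    found <- TRUE
    st0 <- strucheck(base$chain, ref)$stats
    st1 <- strucheck(plus_sub$chain, ref)$stats
    expect_gte(st1$n_variations, st0$n_variations)
    expect_equal(st1$n_missing, st0$n_missing)
    st_none <- strucheck(perfect_fixture(100, seed)$chain, ref)$stats
    expect_gte(st0$n_missing, st_none$n_missing)
    break
  }
  expect_true(found)
})
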