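test_that("a minimal single-chain file parses into its residue sequence", {
  lines <- pdb_text(atom_line(1, "MET", "A", 1),
                    atom_line(2, "ALA", "A", 2),
                    atom_line(3, "GLY", "A", 3))
  m <- read_pdb(lines)
  expect_named(m$chains, "A")
  ch <- m$chains[["A"]]
  expect_equal(ch$sequence, "MAG")
  expect_equal(ch$residues$res_seq, 1:3)
  expect_equal(ch$residues$order_index, 0:2)
  expect_equal(ch$residues$icode, rep("", 3))
})

test_that("only the first MODEL of a multi-model file is read", {
  lines <- c("MODEL        1",
             atom_line(1, "MET", "A", 1), atom_line(2, "ALA", "A", 2),
             "ENDMDL",
             "MODEL        2",
             atom_line(3, "GLY", "B", 1),
             "ENDMDL", "END")
  m <- read_pdb(lines)
  expect_named(m$chains, "A")
  expect_equal(m$chains[["A"]]$sequence, "MA")
  expect_equal(m$model_number, 1L)
})

test_that("altlocs collapse to one residue; HETATM and waters are excluded", {
  lines <- pdb_text(
    atom_line(1, "SER", "A", 1, altloc = "A"),
    atom_line(2, "SER", "A", 1, altloc = "B"),
    atom_line(3, "GLY", "A", 2),
    atom_line(4, "HOH", "A", 101, record = "HETATM"),
    atom_line(5, "MSE", "A", 3, record = "HETATM")
  )
  m <- read_pdb(lines)
  expect_equal(m$chains[["A"]]$sequence, "SG")
  m2 <- read_pdb(lines, include_modified = TRUE)
  expect_equal(m2$chains[["A"]]$sequence, "SGM")
})

test_that("unknown residue names map to X; conflicting duplicates warn", {
  m <- read_pdb(pdb_text(atom_line(1, "MET", "A", 1),
                         atom_line(2, "FOO", "A", 2)))
  expect_equal(m$chains[["A"]]$sequence, "MX")
  expect_warning(
    m3 <- read_pdb(pdb_text(atom_line(1, "MET", "A", 1),
                            atom_line(2, "ALA", "A", 1),
                            atom_line(3, "GLY", "A", 2))),
    "duplicate"
  )
  expect_equal(m3$chains[["A"]]$sequence, "MG")
})

test_that("empty or malformed input raises informative parse errors", {
  expect_error(read_pdb(c("REMARK 1", "END")), "no ATOM records")
  bad <- atom_line(1, "MET", "A", 1)
  substr(bad, 23, 26) <- " 1a "
  expect_error(read_pdb(c("REMARK 1", bad, "END")),
               "columns 23-26 at line 2")
})

test_that("extract_chain_sequence finds the chain or lists what exists", {
  m <- read_pdb(pdb_text(atom_line(1, "MET", "A", 1)))
  expect_equal(extract_chain_sequence(m, "A")$chain_id, "A")
  expect_error(extract_chain_sequence(m, "Z"), "available chains: A")
})

test_that("identity renumbering preserves chain atom lines byte for byte", {
  fx <- apply_edits(make_reference(50, 7), edit_plan())
  lines <- emit_pdb(fx$chain)
  m <- read_pdb(lines)
  ids <- structure_id(fx$chain$residues$res_seq, fx$chain$residues$icode)
  idmap <- stats::setNames(fx$chain$residues$res_seq, ids)
  out <- write_renumbered_pdb(m, "A", idmap)
  atom_in <- lines[startsWith(lines, "ATOM")]
  atom_out <- out[startsWith(out, "ATOM")]
  expect_identical(atom_out, atom_in)
  re <- read_pdb(out)$chains[["A"]]
  expect_identical(re$residues, m$chains[["A"]]$residues)
  expect_identical(re$sequence, m$chains[["A"]]$sequence)
})

test_that("a +96 shift appears verbatim in the re-parsed numbering", {
  fx <- apply_edits(make_reference(50, 7), edit_plan())
  m <- read_pdb(emit_pdb(fx$chain))
  ids <- structure_id(fx$chain$residues$res_seq, fx$chain$residues$icode)
  shifted <- stats::setNames(fx$chain$residues$res_seq + 96L, ids)
  out <- write_renumbered_pdb(m, "A", shifted)
  re <- read_pdb(out)$chains[["A"]]
  expect_equal(re$residues$res_seq, fx$chain$residues$res_seq + 96L)
})

test_that("dropped residues are removed with a warning", {
  fx <- apply_edits(make_reference(30, 2), edit_plan())
  m <- read_pdb(emit_pdb(fx$chain))
  ids <- structure_id(fx$chain$residues$res_seq, fx$chain$residues$icode)
  map <- stats::setNames(fx$chain$residues$res_seq, ids)
  map[10] <- NA
  expect_warning(out <- write_renumbered_pdb(m, "A", map), "removed")
  expect_equal(nrow(read_pdb(out)$chains[["A"]]$residues), 29)
})

test_that("renumber maps must cover the chain and respect the field width", {
  fx <- apply_edits(make_reference(10, 2), edit_plan())
  m <- read_pdb(emit_pdb(fx$chain))
  ids <- structure_id(fx$chain$residues$res_seq, fx$chain$residues$icode)
  map <- stats::setNames(fx$chain$residues$res_seq, ids)
  expect_error(write_renumbered_pdb(m, "A", map[-1]), "lacks entries")
  map_big <- map + 99990L
  expect_error(write_renumbered_pdb(m, "A", map_big), "formatting error")
})

test_that("only the selected chain is written, with a REMARK header", {
  lines <- pdb_text(atom_line(1, "MET", "A", 1),
                    atom_line(2, "GLY", "B", 1))
  m <- read_pdb(lines)
  out <- write_renumbered_pdb(m, "A", c("1" = 5L), accession = "P12345")
  expect_match(out[1], "^REMARK 999 .*P12345")
  expect_false(any(grepl(" B ", out, fixed = TRUE)))
  expect_equal(read_pdb(out)$chains[["A"]]$residues$res_seq, 5L)
})

test_that("sequence extraction agrees with an independent PDB reader", {
  fx <- apply_edits(make_reference(60, 5), edit_plan(numbering_offset = 4L))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(emit_pdb(fx$chain), path)
  ours <- read_pdb(path)$chains[["A"]]
  ext <- bio3d::read.pdb(path, verbose = FALSE)
  ext_seq <- paste(bio3d::pdbseq(ext), collapse = "")
  expect_equal(ours$sequence, ext_seq)
  ca <- ext$atom[ext$atom$elety == "CA", ]
  expect_equal(ours$residues$res_seq, ca$resno)
})
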