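---
title: "Checking structure models against reference sequences"
author: "strucheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checking structure models against reference sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucheck)
```

## The problem

Sequence databases are updated continuously; structure resources — predicted
models in particular — are rebuilt far less often. A model built from a
superseded sequence record may lack residues the current record contains,
carry residues the record no longer has, or differ at individual positions.
Independently of the sequence, the *author residue numbers* inside a PDB
file are free labels: nothing forces residue "107" of a model to be residue
107 of the UniProt record. Both failure modes silently corrupt any analysis
that maps positional annotations (variants, domains, binding or modification
sites) onto the structure.

`strucheck` makes both checks explicit. Given a structure file and a
reference sequence it answers two questions per chain:

1. **Does the structure's amino-acid sequence match the reference?**
2. **Do the author residue numbers agree with the reference positions?**

and, where they do not, produces a per-residue discrepancy table and a
renumbered structure in reference coordinates.

## The pipeline

`strucheck()` runs four steps, each available as a standalone function:

1. **Sequence extraction** (`read_pdb()`, `extract_chain_sequence()`). One
   residue is recorded per distinct (chain, residue number, insertion code)
   triple among the ATOM records, in order of first appearance. Only the
   first MODEL of a multi-model file is used — the sequence is identical
   across models, and a deterministic choice keeps outputs reproducible.
   Alternate locations collapse to the first atom seen: sequence extraction
   needs residue existence, not coordinates. HETATM records are excluded by
   default; `include_modified = TRUE` admits selenomethionine and friends
   (MSE→M, SEC→U, PYL→O). Unknown residue names become `X`, which can never
   count as an identity in the alignment.

2. **Global alignment** (`global_align()`). Needleman–Wunsch over the full
   lengths of both sequences, linear gap scoring, defaults match = 1,
   mismatch = 0, gap = 0. These defaults deliberately mirror the common
   library default for this task; they are configurable
   (`scoring_scheme()`).

3. **Classification** (`classify()`). Every alignment column becomes one
   row of the residue table: reference-only columns are `missing`,
   structure-only columns are `insertion`, aligned pairs are `ID match`
   when the author number equals the reference position and the insertion
   code is blank, otherwise `ID mismatch`. Aligned pairs with different
   amino acids carry a `variation` flag.

4. **Summary and renumbering** (`summarize_mapping()`,
   `build_renumber_plan()`, `write_renumbered_pdb()`). Aligned residues are
   assigned their reference position; insertions have no reference position
   and are dropped from the renumbered file — preserving a one-to-one
   mapping — with a warning. Only the residue-number columns (23–26) and the
   insertion-code column (27) of each retained ATOM line are rewritten;
   every other byte is preserved.

## Degenerate scoring and the deterministic tie-break

With match = 1 and free gaps/mismatches, the optimal score is simply the
longest common subsequence of the two sequences, and co-optimal alignments
are plentiful (a mismatch column costs exactly as much as a gap–gap pair:
nothing). A reporting tool must nevertheless print *one* alignment, the
same one every run. `global_align()` therefore applies a fixed preference —
diagonal over up (gap in the structure) over left (gap in the reference) —
at every traceback cell. Two consequences are worth knowing:

* The result is exactly the co-optimal alignment whose traceback move
  string is lexicographically smallest under that preference; the test
  suite verifies this against exhaustive enumeration of all alignments for
  a thousand random short pairs per run.
* Symmetry properties (swapping the two sequences mirrors missing and
  insertion columns) hold whenever the optimum is unique — which it is for
  the package's fixtures by construction — but not for arbitrary unrelated
  strings, where the direction-dependent tie-break may select differently
  shaped co-optimal alignments.

## Summary statistics

The percent identity reported first is *identical aligned pairs over all
alignment columns* — a single number that penalises both variations and
missing/inserted regions; the identity over aligned pairs only is kept as a
secondary field (`identity_pct_aligned`). The "gaps" count reported is the
number of maximal gap *runs* (indel events); the gapped-column count is
stored alongside. Three count identities hold by construction and are
asserted on every fixture:

* `n_id_match + n_id_mismatch + n_insertions = n_struct_residues`
* `n_id_match + n_id_mismatch + n_missing = reference length`
* `aln_length = n_struct_residues + n_missing = reference length + n_insertions`

The sequence assessment is green only for 100% identity *and* full
coverage (no gap columns): a pristine fragment is still flagged, because
annotations over the absent region have nowhere to land. The identifier
assessment is green when no aligned residue mismatches its reference
position and there are no insertions; missing residues are allowed, since
they cannot receive a wrongly-placed annotation.

## Input limits

Custom structure files above 5 MB are blocked (reporting tools should not
silently chew through arbitrarily large uploads), as are database-sourced
entries longer than 2,700 residues — a constraint of the upstream model
APIs, whose files are split beyond that length. Local reference FASTA files
of any length are accepted. `validate_limits()` returns the blocking
warnings; `run_check()` enforces them before any computation.

## The fixture generator

`make_reference()` draws a reference uniformly over the 20 standard amino
acids from a seeded generator; `apply_edits()` derives a structure chain
from it by terminal truncations, internal deletions, substitutions,
insertions, numbering offsets, insertion codes, or sequential renumbering
(`renumber_from`, emulating model files numbered 1..n regardless of
coverage). The generator returns the by-construction mapping rows, so it is
an *oracle*: the full pipeline must recover every label exactly.

That guarantee requires the constructed alignment to be the unique optimum,
and under the degenerate default scoring the commonly assumed spacing rule
(edits two positions apart) is not sufficient. `edit_plan()` validation
therefore enforces, beyond disjointness and spacing:

* the residue type immediately left of a deleted block must not recur
  inside the block (otherwise the gap can slide or fragment at equal
  score);
* substituted and inserted residue types must not occur in any deleted
  block (otherwise they can pair into the block at a strictly better
  score);
* the residue type left of an insertion must not recur in the inserted
  segment;
* a deleted block and an insertion separated by a bridge of at most ten
  unedited residues must have mutually type-disjoint block, bridge and
  inserted segment (the block frees reference slots and the insertion
  supplies query residues, enabling equal-score re-pairings through short
  bridges).

Plans violating these are rejected as ambiguous rather than producing
ground truth the aligner cannot be expected to reproduce.
`random_edit_plan()` resamples deterministically under its seed until a
valid plan is found. `twin_fixture()` — a 478-residue reference with a
96-residue deletion spanning positions 11..106, two substitutions near the
N-terminus, and sequential numbering from 1 — draws the deleted block from
a residue-type alphabet disjoint from the N-terminal segment so these
conditions hold by construction; it reproduces the characteristic
arithmetic of a model built from a superseded record: 382 modelled
residues, a 96-residue missing run, two variations, and reference position
107 carrying structure number 11.

What the generator does *not* emulate: real coordinates and geometry
(fixtures are CA-only traces on a line), B-factors/confidence values,
modified residues, multi-chain complexes, and — importantly — the natural
repetitiveness of real sequences, where genuinely ambiguous co-optimal
alignments can occur. Passing the fixture suite shows the machinery is
exact where a unique answer exists; on real repetitive sequences the
reported alignment is *a* deterministic optimum, not the only one.

## Numerical and edge-case choices

* Score comparisons in the traceback use an absolute tolerance of 1e-9,
  relevant only for non-integer user-supplied scores.
* Residue numbers are parsed from fixed columns 23–26 (insertion code 27);
  negative and duplicate author numbers are accepted on input, duplicates
  differing only by altloc collapse silently, true duplicates (same key,
  different residue name) keep the first occurrence with a warning.
* Renumbered output must fit the four-column field: targets outside
  −999..9999 are a formatting error.
* TSV absent cells are blank (not "NA"); JSON uses `null`; percent identity
  is serialised with two decimals; key order is fixed so identical inputs
  give identical bytes.
* Empty mappings cannot be summarised (error), and empty sequences cannot
  be aligned (error).

## Problem sizes used by the test suite

The property suite enumerates all global alignments for 1,000 random pairs
of length ≤ 8 over a four-letter alphabet (exhaustive enumeration is the
score and tie-break oracle), recovers ground truth on 100 random edit plans
over references of length 60–140, and re-checks renumbered structures for
idempotence; the synthetic twin runs at the full 478-residue scale. These
sizes exercise every code path while keeping the suite comfortably
desk-scale.

## Known limitations

* PDB format only; mmCIF/BinaryCIF input is out of scope.
* One chain is checked and renumbered at a time.
* The reference fetch requires network access; all computation is
  offline-first (everything downstream takes a `reference_sequence`
  value), and fetched sequences are cached with their retrieval date.
* Assessments are binary by design; the residue table is the instrument
  for anything finer.
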