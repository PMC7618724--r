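# Independent oracles used across the suite.

# Exhaustive enumeration of every global alignment of s1 and s2 (all
# monotone lattice paths), scored move by move. Among the co-optimal
# alignments the winner is the lexicographically smallest traceback move
# string under diagonal(1) < up(2) < left(3), which is exactly the
# "preference applied at every traceback cell" rule. Breadth-first over
# backward path prefixes; no dynamic programming is shared with the
# implementation under test.
# Move strings are tracked as exact base-4 fractions (digit k at weight
# 4^-k), so the lexicographically smallest traceback string is simply the
# numerically smallest key; paths are at most m+n <= 16 moves, well within
# exact double arithmetic.
oracle_align <- function(s1, s2, match = 1, mismatch = 0, gap = 0) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  st_i <- length(a); st_j <- length(b); st_s <- 0; st_k <- 0
  fin_s <- numeric(0); fin_k <- numeric(0)
  depth <- 0
  while (length(st_i)) {
    done <- st_i == 0 & st_j == 0
    if (any(done)) {
      fin_s <- c(fin_s, st_s[done])
      fin_k <- c(fin_k, st_k[done])
    }
    st_i <- st_i[!done]; st_j <- st_j[!done]
    st_s <- st_s[!done]; st_k <- st_k[!done]
    if (!length(st_i)) break
    depth <- depth + 1
    w <- 4^(-depth)
    d_ok <- st_i > 0 & st_j > 0
    u_ok <- st_i > 0
    l_ok <- st_j > 0
    ns <- c(st_s[d_ok] + ifelse(a[st_i[d_ok]] == b[st_j[d_ok]], match, mismatch),
            st_s[u_ok] + gap,
            st_s[l_ok] + gap)
    nk <- c(st_k[d_ok] + 1 * w, st_k[u_ok] + 2 * w, st_k[l_ok] + 3 * w)
    ni <- c(st_i[d_ok] - 1L, st_i[u_ok] - 1L, st_i[l_ok])
    nj <- c(st_j[d_ok] - 1L, st_j[u_ok], st_j[l_ok] - 1L)
    st_i <- ni; st_j <- nj; st_s <- ns; st_k <- nk
  }
  best <- max(fin_s)
  key <- min(fin_k[fin_s >= best - 1e-9])
  moves <- integer(0)
  while (key > 1e-12) {
    key <- key * 4
    d <- floor(key + 1e-9)
    moves <- c(moves, d)
    key <- key - d
  }
  list(score = best, moves = paste(moves, collapse = ""))
}

# Convert a traceback-order move string into alignment columns (forward).
oracle_columns <- function(moves, s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  mv <- rev(strsplit(moves, "")[[1]])
  i <- 0L; j <- 0L
  ra <- character(length(mv)); qa <- character(length(mv))
  for (k in seq_along(mv)) {
    if (mv[k] == "1") {
      i <- i + 1L; j <- j + 1L; ra[k] <- a[i]; qa[k] <- b[j]
    } else if (mv[k] == "2") {
      i <- i + 1L; ra[k] <- a[i]; qa[k] <- "-"
    } else {
      j <- j + 1L; ra[k] <- "-"; qa[k] <- b[j]
    }
  }
  data.frame(ref_aa = ra, query_aa = qa, stringsAsFactors = FALSE)
}

# Canonical signature of an alignment for equality checks.
aln_signature <- function(columns) {
  paste(paste0(columns$ref_aa, columns$query_aa), collapse = " ")
}

# Parse the TSV residue table back into mapping rows (round-trip oracle).
parse_mapping_tsv <- function(text) {
  df <- utils::read.delim(text = text, sep = "\t", colClasses = "character",
                          check.names = FALSE)
  data.frame(
    alignment_id = as.integer(df[["Alignment ID"]]),
    uniprot_aa = ifelse(df[["UniProt residue AA"]] == "", NA_character_,
                        df[["UniProt residue AA"]]),
    uniprot_id = suppressWarnings(as.integer(df[["UniProt residue ID"]])),
    structure_aa = ifelse(df[["Structure residue AA"]] == "", NA_character_,
                          df[["Structure residue AA"]]),
    structure_id = ifelse(df[["Structure residue ID"]] == "", NA_character_,
                          df[["Structure residue ID"]]),
    label = df[["label"]],
    stringsAsFactors = FALSE
  )
}

# Strip row names so data-frame comparisons look at content only.
unrowname <- function(df) {
  row.names(df) <- NULL
  df
}

# Longest run of a given label in mapping rows.
max_label_run <- function(rows, lab) {
  r <- rle(rows$label == lab)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}
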