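## Independent oracles and fixture builders. Everything here works from raw
## characters with its own lookup tables, never through the package's
## encoding helpers, so oracle agreement is a real cross-check.

ORACLE_BASES <- c("A", "C", "G", "T")

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = character())

## naive per-column p-distance with pairwise deletion
oraclePDistance <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- 0L
  mm <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] %in% ORACLE_BASES && cb[k] %in% ORACLE_BASES) {
      n <- n + 1L
      if (ca[k] != cb[k]) mm <- mm + 1L
    }
  }
  if (n == 0L) list(distance = NA_real_, nSites = 0L)
  else list(distance = mm / n, nSites = n)
}

## residue set of a species at one column (characters of its members)
oracleResidueSet <- function(chars) {
  sort(unique(unlist(ORACLE_IUPAC[chars], use.names = FALSE)))
}

## minimal IUPAC symbol for a base set
oracleConsensusSymbol <- function(set) {
  if (length(set) == 0L) return("-")
  key <- paste(sort(set), collapse = "")
  keys <- vapply(ORACLE_IUPAC, function(s) paste(sort(s), collapse = ""), "")
  names(keys)[match(key, keys)]
}

## diagnostic columns for `target` from a character matrix + species vector
oracleDiagnosticColumns <- function(M, species, target) {
  out <- integer()
  for (j in seq_len(ncol(M))) {
    own <- oracleResidueSet(M[species == target, j])
    others <- oracleResidueSet(M[species != target, j])
    if (length(own) > 0L && length(intersect(own, others)) == 0L) {
      out <- c(out, j)
    }
  }
  out
}

## exhaustive window enumeration: every (start, end) pair of diagnostic
## columns whose internal merge gaps are <= mergeGap and which holds at
## least minDiag diagnostic columns; keep the maximal (non-contained) ones
oracleFragmentSpans <- function(diagCols, minDiag, mergeGap) {
  empty <- data.frame(start = integer(), end = integer(),
    nDiagnostic = integer())
  m <- length(diagCols)
  if (m == 0L) return(empty)
  cand <- list()
  for (i in seq_len(m)) {
    for (j in i:m) {
      cols <- diagCols[i:j]
      if (length(cols) < minDiag) next
      if (length(cols) > 1L && any(diff(cols) - 1L > mergeGap)) next
      cand[[length(cand) + 1L]] <- c(s = diagCols[i], e = diagCols[j],
        nd = length(cols))
    }
  }
  if (length(cand) == 0L) return(empty)
  tab <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(tab)), function(r) {
    !any(tab[, "s"] <= tab[r, "s"] & tab[, "e"] >= tab[r, "e"] &
      (tab[, "s"] != tab[r, "s"] | tab[, "e"] != tab[r, "e"]))
  }, logical(1L))
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab[, "s"]), , drop = FALSE]
  data.frame(start = unname(tab[, "s"]), end = unname(tab[, "e"]),
    nDiagnostic = unname(tab[, "nd"]))
}

## full oracle fragment table (span + sequence) for one target species
oracleFragments <- function(M, species, target, minDiag, mergeGap) {
  dcols <- oracleDiagnosticColumns(M, species, target)
  spans <- oracleFragmentSpans(dcols, minDiag, mergeGap)
  spans$sequence <- vapply(seq_len(nrow(spans)), function(r) {
    syms <- vapply(spans$start[r]:spans$end[r], function(j) {
      oracleConsensusSymbol(oracleResidueSet(M[species == target, j]))
    }, "")
    paste(syms[syms != "-"], collapse = "")
  }, "")
  spans
}

## species-structured random alignment with ambiguity codes and gaps
randomSpeciesAlignment <- function(nSpecies, membersPerSpecies, L,
    pMut = 0.08, pAmb = 0.04, pGap = 0.05) {
  amb <- c("R", "Y", "S", "W", "K", "M", "N")
  ids <- character()
  rows <- character()
  species <- character()
  for (s in seq_len(nSpecies)) {
    root <- sample(ORACLE_BASES, L, replace = TRUE)
    for (m in seq_len(membersPerSpecies)) {
      r <- root
      i <- runif(L) < pMut
      r[i] <- sample(ORACLE_BASES, sum(i), replace = TRUE)
      i <- runif(L) < pAmb
      r[i] <- sample(amb, sum(i), replace = TRUE)
      i <- runif(L) < pGap
      r[i] <- "-"
      ids <- c(ids, sprintf("s%02d_m%02d", s, m))
      rows <- c(rows, paste(r, collapse = ""))
      species <- c(species, sprintf("sp%02d", s))
    }
  }
  names(rows) <- ids
  list(
    alignment = BarcodeAlignment(rows),
    labels = SpeciesLabelMap(data.frame(id = ids, species = species,
      material = "specimen", reliable = TRUE, stringsAsFactors = FALSE)),
    species = species,
    M = do.call(rbind, strsplit(rows, "", fixed = TRUE)))
}

## write a small FASTA/TSV fixture pair into a temp dir
writeToyDataset <- function(seqs, labelsDf, dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "aln.fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  tsv <- file.path(dir, "labels.tsv")
  write.table(labelsDf, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, labels = tsv, dir = dir)
}
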