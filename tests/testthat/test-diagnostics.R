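## two species over a hand-built alignment; species P has controlled
## variant columns against a constant species Q background
.profileFixture <- function(rowsP, rowsQ) {
  seqs <- c(setNames(rowsP, paste0("p", seq_along(rowsP))),
    setNames(rowsQ, paste0("q", seq_along(rowsQ))))
  aln <- BarcodeAlignment(seqs)
  labels <- SpeciesLabelMap(data.frame(id = names(seqs),
    species = rep(c("P", "Q"), c(length(rowsP), length(rowsQ))),
    material = "specimen", reliable = TRUE))
  columnProfiles(aln, labels)
}

test_that("column profiles expand ambiguity codes and count gaps", {
  prof <- .profileFixture(c("AAT", "AWT", "A-T"), c("CCC", "CCC"))
  ## column 1: members {A, A, A}; column 2: {A, W = {A,T}, gap}
  expect_identical(speciesConsensus(prof, "P"), c("A", "W", "T"))
  expect_identical(unname(prof@gapCounts["P", ]), c(0L, 1L, 0L))
  expect_identical(unname(prof@memberCounts["P"]), 3L)
  ## all-gap column yields an empty residue set
  prof2 <- .profileFixture(c("-A", "-A"), c("CC", "CC"))
  expect_identical(speciesConsensus(prof2, "P"), c("-", "A"))
})

test_that("consensus symbols are the minimal IUPAC code for the set", {
  prof <- .profileFixture(
    c("ACGTA", "ATGTC", "ACGTG"), # sets {A},{C,T},{G},{T},{A,C,G}
    c("TTTTT", "TTTTT"))
  expect_identical(speciesConsensus(prof, "P"), c("A", "Y", "G", "T", "V"))
  profN <- .profileFixture(c("A", "C", "G", "T"), c("A", "A"))
  expect_identical(speciesConsensus(profN, "P"), "N")
})

test_that("diagnostic columns require exclusive residue sets", {
  ## col1: P={A} vs Q={C} -> diagnostic for both sides
  ## col2: P={A,T} (W) vs Q={A} -> shared A, not diagnostic
  ## col3: P={C} vs Q all-gapped -> diagnostic (indel presence/absence)
  ## col4: identical -> not diagnostic
  prof <- .profileFixture(c("AACG", "ATCG"), c("CA-G", "CA-G"))
  expect_identical(diagnosticColumns(prof, "P"), c(1L, 3L))
  expect_identical(diagnosticColumns(prof, "Q"), 1L)
  expect_error(diagnosticColumns(prof, "R"), "not profiled")
})

test_that("fragment assembly merges, trims and filters by minDiag", {
  ## background identical; P differs at chosen columns only
  base <- strsplit(paste(rep("A", 30), collapse = ""), "")[[1]]
  mk <- function(at) {
    s <- base; s[at] <- "C"; paste(s, collapse = "")
  }
  q <- paste(base, collapse = "")

  ## adjacent diagnostic columns {10, 11}
  prof <- .profileFixture(c(mk(c(10, 11)), mk(c(10, 11))), c(q, q))
  f <- assembleFragments(prof, "P", minDiag = 2, mergeGap = 4)
  expect_identical(nrow(f), 1L)
  expect_identical(f$start, 10L)
  expect_identical(f$end, 11L)
  expect_identical(f$nDiagnostic, 2L)
  expect_identical(f$sequence, "CC")

  ## isolated columns {10, 20} each fall below minDiag
  prof <- .profileFixture(c(mk(c(10, 20)), mk(c(10, 20))), c(q, q))
  expect_identical(nrow(assembleFragments(prof, "P", 2, 4)), 0L)

  ## interleaved {10, 12, 14} merges into one span with consensus filler
  prof <- .profileFixture(c(mk(c(10, 12, 14)), mk(c(10, 12, 14))), c(q, q))
  f <- assembleFragments(prof, "P", 2, 4)
  expect_identical(f$start, 10L)
  expect_identical(f$end, 14L)
  expect_identical(f$nDiagnostic, 3L)
  expect_identical(f$sequence, "CACAC")

  expect_error(assembleFragments(prof, "P", minDiag = 1), "at least 2")
})

test_that("gapped target columns inflate the span beyond the sequence", {
  ## P diagnostic at 5 and 9, entirely gapped at 6-8
  rowsP <- c("AAAAC---CAAA", "AAAAC---CAAA")
  rowsQ <- c("AAAAGTTTGAAA", "AAAAGTTTGAAA")
  prof <- .profileFixture(rowsP, rowsQ)
  f <- assembleFragments(prof, "P", 2, 4)
  expect_identical(f$start, 5L)
  expect_identical(f$end, 9L)
  expect_identical(f$sequence, "CC")
  expect_gte(f$end - f$start + 1L, nchar(f$sequence))
})

test_that("fragments per species are sorted and non-overlapping", {
  set.seed(33)
  for (rep in 1:10) {
    toy <- randomSpeciesAlignment(3, 3, 60)
    prof <- columnProfiles(toy$alignment, toy$labels)
    for (sp in prof@species) {
      f <- assembleFragments(prof, sp, 2, 3)
      if (nrow(f) > 1) {
        expect_true(all(diff(f$start) > 0))
        expect_true(all(f$start[-1] > f$end[-nrow(f)]))
      }
      expect_true(all(f$end - f$start + 1L >= nchar(f$sequence)))
    }
  }
})

test_that("assembly matches the exhaustive window oracle on random data", {
  set.seed(44)
  for (rep in 1:25) {
    toy <- randomSpeciesAlignment(sample(2:5, 1), sample(1:4, 1),
      sample(30:70, 1))
    mergeGap <- sample(0:6, 1)
    target <- sample(unique(toy$species), 1)
    prof <- columnProfiles(toy$alignment, toy$labels)
    expect_identical(diagnosticColumns(prof, target),
      oracleDiagnosticColumns(toy$M, toy$species, target))
    got <- assembleFragments(prof, target, 2, mergeGap)
    want <- oracleFragments(toy$M, toy$species, target, 2, mergeGap)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$nDiagnostic, want$nDiagnostic)
    expect_identical(got$sequence, want$sequence)
  }
})

test_that("planted species-unique fragments are always recovered", {
  for (seed in 1:5) {
    sim <- simulateBarcodeData(nSpecies = 3, membersPerSpecies = 4,
      nColumns = 300, pIntra = 0.004, pInter = 0.04,
      plantedFragments = list(
        list(species = "Species02", columns = c(50, 52, 54), bases = "TTT")),
      seed = 300 + seed)
    frags <- diagnosticFragments(sim$alignment, sim$truth$cleanLabels)
    hit <- frags[frags$species == "Species02" & frags$start <= 50 &
      frags$end >= 54, ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("joint labelling interleaves species by alignment position", {
  base <- strsplit(paste(rep("A", 40), collapse = ""), "")[[1]]
  mk <- function(at, ch) { s <- base; s[at] <- ch; paste(s, collapse = "") }
  ## third species keeps the background so diagnosticity is one-sided
  seqs <- c(p1 = mk(c(5, 6), "C"), p2 = mk(c(5, 6), "C"),
    q1 = mk(c(20, 21), "G"), q2 = mk(c(20, 21), "G"),
    r1 = paste(base, collapse = ""), r2 = paste(base, collapse = ""))
  aln <- BarcodeAlignment(seqs)
  labels <- SpeciesLabelMap(data.frame(id = names(seqs),
    species = rep(c("P", "Q", "R"), each = 2), material = "specimen",
    reliable = TRUE))
  frags <- diagnosticFragments(aln, labels)
  expect_identical(frags$label, c("A", "B"))
  expect_identical(frags$species, c("P", "Q"))
  expect_identical(frags$start, c(5L, 20L))
})
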