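test_that("pairwise p-distance applies pairwise deletion", {
  expect_identical(pairwisePDistance("ACGT", "ACGT"),
    list(distance = 0, nSites = 4L))
  expect_identical(pairwisePDistance("ACGT", "TGCA"),
    list(distance = 1, nSites = 4L))
  ## column 3 gapped -> deleted; one mismatch over 4 compared columns
  expect_identical(pairwisePDistance("AC-GT", "AAAGT"),
    list(distance = 0.25, nSites = 4L))
  ## ambiguity codes count as missing data
  expect_identical(pairwisePDistance("ACGT", "ACGY"),
    list(distance = 0, nSites = 3L))
  expect_identical(pairwisePDistance("----", "ACGT"),
    list(distance = NA_real_, nSites = 0L))
  expect_error(pairwisePDistance("ACG", "ACGT"), "equal")
})

test_that("distance matrix is symmetric with flagged undefined entries", {
  aln <- BarcodeAlignment(c(a = "ACGT", b = "ACGA", c = "TCGA"))
  pdm <- pDistanceMatrix(aln)
  d <- distValues(pdm)
  expect_equal(unname(d["a", "b"]), 0.25)
  expect_equal(unname(d["a", "c"]), 0.5)
  expect_equal(unname(d["b", "c"]), 0.25)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))

  same <- BarcodeAlignment(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  expect_true(all(distValues(pDistanceMatrix(same)) == 0))

  disjoint <- BarcodeAlignment(c(a = "AC--", b = "--GT"))
  pd <- pDistanceMatrix(disjoint)
  expect_true(is.na(distValues(pd)["a", "b"]))
  expect_identical(unname(siteCounts(pd)["a", "b"]), 0L)

  expect_error(pDistanceMatrix(BarcodeAlignment(c(a = "ACGT"))),
    "at least 2")
})

test_that("appending gapped or ambiguous columns never changes a distance", {
  set.seed(42)
  alphabet <- c("A", "C", "G", "T", "R", "Y", "N", "-")
  for (rep in 1:50) {
    L <- sample(5:40, 1)
    a <- paste(sample(alphabet, L, TRUE), collapse = "")
    b <- paste(sample(alphabet, L, TRUE), collapse = "")
    base <- pairwisePDistance(a, b)
    ## extra column missing in at least one member
    extras <- list(c("-", "A"), c("N", "C"), c("-", "-"), c("G", "W"))
    for (e in extras) {
      expect_identical(pairwisePDistance(paste0(a, e[1]), paste0(b, e[2])),
        base)
    }
  }
})

test_that("duplicating every column preserves distances, doubles sites", {
  set.seed(43)
  toy <- randomSpeciesAlignment(2, 3, 30)
  rows <- as.character(toy$alignment@seqs)
  dup <- BarcodeAlignment(vapply(rows, function(s) {
    paste(rep(strsplit(s, "")[[1]], each = 2), collapse = "")
  }, "", USE.NAMES = TRUE))
  p1 <- pDistanceMatrix(toy$alignment)
  p2 <- pDistanceMatrix(dup)
  expect_identical(distValues(p1), distValues(p2))
  expect_identical(siteCounts(p2), siteCounts(p1) * 2L)
})

test_that("distance engine agrees with ape on an ambiguity-free alignment", {
  skip_if_not_installed("ape")
  set.seed(7)
  toy <- randomSpeciesAlignment(3, 3, 50, pAmb = 0, pGap = 0.08)
  pdm <- pDistanceMatrix(toy$alignment)
  bin <- ape::as.DNAbin(strsplit(tolower(as.character(toy$alignment@seqs)),
    ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
    pairwise.deletion = TRUE))
  expect_equal(unname(distValues(pdm)), unname(ref[seqIds(pdm), seqIds(pdm)]),
    tolerance = 1e-12)
})

test_that("bootstrap SE is zero for identical pairs and seed-reproducible", {
  aln <- BarcodeAlignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGAACGA"))
  expect_identical(bootstrapSE(aln, c("a", "b"), 200, seed = 5), 0)
  s1 <- bootstrapSE(aln, c("a", "c"), 500, seed = 9)
  s2 <- bootstrapSE(aln, c("a", "c"), 500, seed = 9)
  expect_identical(s1, s2)
  expect_gt(s1, 0)

  none <- BarcodeAlignment(c(a = "----", b = "ACGT"))
  expect_true(is.na(bootstrapSE(none, c("a", "b"), 100, seed = 1)))
  expect_error(bootstrapSE(aln, c("a", "c"), 100), "seed")
})

test_that("matrix-level bootstrap fills symmetric standard errors", {
  aln <- BarcodeAlignment(c(a = "ACGTACGT", b = "ACGAACGA", c = "ACGTACGA"))
  pdm <- pDistanceMatrix(aln, bootstrapReplicates = 300, seed = 3)
  se <- bootstrapSEs(pdm)
  expect_identical(se, t(se))
  expect_true(all(!is.na(se[upper.tri(se)])))
  expect_error(pDistanceMatrix(aln, bootstrapReplicates = 10), "seed")
})

test_that("distance writers emit square and long tables", {
  aln <- BarcodeAlignment(c(a = "ACGT", b = "ACGA", c = "TCGA"))
  pdm <- pDistanceMatrix(aln)
  sq <- tempfile(); lg <- tempfile()
  long <- writeDistanceMatrix(pdm, sq, lg, percent = TRUE)
  expect_identical(nrow(long), 3L)
  expect_setequal(colnames(read.delim(lg)),
    c("id_i", "id_j", "distance", "n_sites", "se"))
  tab <- read.delim(lg, colClasses = "character")
  expect_identical(tab$distance[tab$id_i == "a" & tab$id_j == "c"], "50.00")
  sqTab <- read.delim(sq, check.names = FALSE)
  expect_identical(colnames(sqTab), c("id", "a", "b", "c"))
})
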