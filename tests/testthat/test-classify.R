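## toy panel geometry over L = 1000 columns:
## refA = root; refB = root with 30 substitutions (d = 0.030)
## queries are crafted relative to these anchors
.makeClassifyFixture <- function() {
  set.seed(101)
  root <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  mutate_at <- function(s, at) {
    s[at] <- vapply(s[at], function(b) {
      setdiff(c("A", "C", "G", "T"), b)[1]
    }, "")
    s
  }
  refB <- mutate_at(root, 1:30)
  qMis <- mutate_at(refB, 101:104)      # 0.004 from B, ~0.034 from A
  qFar <- mutate_at(root, seq(11, 990, length.out = 80)) # >= 0.05 anywhere
  qTie <- mutate_at(root, 1:15)         # 0.015 from both A and B
  seqs <- vapply(list(refA = root, refB = refB, qMis = qMis,
    qFar = qFar, qTie = qTie), paste, "", collapse = "")
  aln <- BarcodeAlignment(seqs)
  labels <- SpeciesLabelMap(data.frame(
    id = names(seqs),
    species = c("A", "B", "A", "A", "A"),
    material = c("specimen", "specimen", "strain", "strain", "specimen"),
    reliable = c(TRUE, TRUE, FALSE, FALSE, FALSE)))
  refs <- data.frame(species = c("A", "B"), id = c("refA", "refB"))
  list(aln = aln, labels = labels, refs = refs)
}

test_that("reference panel enforces existence and reliability", {
  fx <- .makeClassifyFixture()
  panel <- buildReferencePanel(fx$aln, fx$labels, fx$refs)
  expect_identical(panel$table$species, c("A", "B"))

  badRel <- fx$refs; badRel$id[1] <- "qMis" # reliable = FALSE
  expect_error(buildReferencePanel(fx$aln, fx$labels, badRel),
    "not flagged reliable")
  badId <- fx$refs; badId$id[2] <- "nope"
  expect_error(buildReferencePanel(fx$aln, fx$labels, badId),
    "not in alignment")
  expect_error(buildReferencePanel(fx$aln, fx$labels,
    list(A = character(0), B = "refB")), "zero designated")

  ## two references for one species are both kept
  two <- rbind(fx$refs, data.frame(species = "A", id = "refA"))
  expect_identical(nrow(buildReferencePanel(fx$aln, fx$labels,
    two)$table), 3L)
})

test_that("classifier separates concordant, mislabeled, gated and tied", {
  fx <- .makeClassifyFixture()
  panel <- buildReferencePanel(fx$aln, fx$labels, fx$refs)
  res <- classifySequences(fx$aln, fx$labels, panel,
    genusCutoff = 0.05, tieEpsilon = 0)
  byId <- function(col) setNames(res[[col]], res$id)

  expect_identical(byId("status")[["refA"]], "concordant")
  expect_equal(byId("dMin")[["refA"]], 0)

  expect_identical(byId("status")[["qMis"]], "mislabeled")
  expect_identical(byId("assigned")[["qMis"]], "B")
  expect_equal(byId("dMin")[["qMis"]], 0.004)

  expect_identical(byId("status")[["qFar"]], "not_in_genus")
  expect_true(is.na(byId("assigned")[["qFar"]]))
  expect_gt(byId("dMin")[["qFar"]], 0.05)

  expect_identical(byId("status")[["qTie"]], "ambiguous")
  expect_true(is.na(byId("assigned")[["qTie"]]))
  expect_identical(byId("runnerUpSpecies")[["qTie"]], "B")
})

test_that("classification is invariant to panel order", {
  fx <- .makeClassifyFixture()
  p1 <- buildReferencePanel(fx$aln, fx$labels, fx$refs)
  p2 <- buildReferencePanel(fx$aln, fx$labels, fx$refs[2:1, ])
  r1 <- classifySequences(fx$aln, fx$labels, p1)
  r2 <- classifySequences(fx$aln, fx$labels, p2)
  expect_equal(r1, r2)
})

test_that("classification errors when a query shares no sites with panel", {
  aln <- BarcodeAlignment(c(ref = "ACGT----", q = "----ACGT"))
  labels <- SpeciesLabelMap(data.frame(id = c("ref", "q"),
    species = c("A", "A"), material = "strain", reliable = TRUE))
  panel <- buildReferencePanel(aln, labels,
    data.frame(species = "A", id = "ref"))
  expect_error(classifySequences(aln, labels, panel, queries = "q"),
    "no comparable sites.*'q'")
})

test_that("mislabel report tallies statuses by material type", {
  fx <- .makeClassifyFixture()
  panel <- buildReferencePanel(fx$aln, fx$labels, fx$refs)
  res <- classifySequences(fx$aln, fx$labels, panel)
  rep <- mislabelReport(res, fx$labels)
  get <- function(m, s) rep$counts$n[rep$counts$material == m &
    rep$counts$status == s]
  expect_identical(get("strain", "mislabeled"), 1L)
  expect_identical(get("strain", "not_in_genus"), 1L)
  expect_identical(get("specimen", "concordant"), 2L)
  expect_identical(get("specimen", "ambiguous"), 1L)
  expect_identical(rep$corrections$id, "qMis")
  expect_identical(rep$corrections$given, "A")
  expect_identical(rep$corrections$assigned, "B")

  emptyRep <- mislabelReport(res[0, ], fx$labels)
  expect_true(all(emptyRep$counts$n == 0L))
  expect_identical(nrow(emptyRep$corrections), 0L)
})

test_that("injected mislabels on well-separated clusters are all recovered", {
  sim <- simulateBarcodeData(nSpecies = 4, membersPerSpecies = 6,
    nColumns = 500, pIntra = 0.004, pInter = 0.05,
    mislabelFraction = 0.125, seed = 202)
  k <- round(0.125 * 24)
  expect_length(sim$truth$swappedIds, k)
  panel <- buildReferencePanel(sim$alignment, sim$labels, sim$references)
  res <- classifySequences(sim$alignment, sim$labels, panel)
  flagged <- res$id[res$status == "mislabeled"]
  expect_setequal(flagged, sim$truth$swappedIds)
  expect_identical(
    res$assigned[match(flagged, res$id)],
    unname(sim$truth$trueSpecies[flagged]))

  ## with truthful labels nothing is flagged
  clean <- classifySequences(sim$alignment, sim$truth$cleanLabels, panel)
  expect_true(all(clean$status == "concordant"))
})
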