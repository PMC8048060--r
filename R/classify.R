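#' Build a panel of reliable reference sequences
#'
#' Assembles the reference panel used by the distance classifier from a
#' species-to-id designation. Every designated id must exist in both the
#' alignment and the label table and be flagged reliable; a designated
#' species with no usable reference is an error.
#'
#' @param alignment a [BarcodeAlignment-class].
#' @param labels the companion [SpeciesLabelMap-class].
#' @param designations a `data.frame` with columns `species` and `id`
#'   (see [readReferenceDesignations()]), or a named list/character vector
#'   mapping species to ids.
#' @return a `list` of class `"ReferencePanel"` with components `table`
#'   (`data.frame`: `species`, `id`) and `enc` (integer-coded residue
#'   matrix of the panel rows).
#' @export
buildReferencePanel <- function(alignment, labels, designations) {
  stopifnot(is(alignment, "BarcodeAlignment"), is(labels, "SpeciesLabelMap"))
  if (!is.data.frame(designations)) {
    none <- names(designations)[lengths(designations) == 0L]
    if (length(none)) {
      stop(sprintf("species with zero designated references: %s",
        paste(none, collapse = ", ")))
    }
    designations <- data.frame(
      species = rep(names(designations), lengths(designations)),
      id = unlist(designations, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  empty <- unique(designations$species[is.na(designations$id) |
    !nzchar(designations$id)])
  if (length(empty)) {
    stop(sprintf("species with zero designated references: %s",
      paste(empty, collapse = ", ")))
  }
  alnIds <- seqIds(alignment)
  missing <- setdiff(designations$id, alnIds)
  if (length(missing)) {
    stop(sprintf("designated reference id not in alignment: %s",
      missing[1L]))
  }
  ld <- labelData(labels)
  rel <- setNames(ld$reliable, ld$id)[designations$id]
  if (anyNA(rel)) {
    stop(sprintf("designated reference id not in label table: %s",
      designations$id[is.na(rel)][1L]))
  }
  if (any(!rel)) {
    stop(sprintf("designated reference is not flagged reliable: %s",
      designations$id[!rel][1L]))
  }
  M <- alignmentMatrix(alignment)[designations$id, , drop = FALSE]
  structure(list(table = designations, enc = .encodeACGTMatrix(M)),
    class = "ReferencePanel")
}

#' Classify sequences against a reference panel
#'
#' Assigns every query to the species of its nearest reference by
#' p-distance (pairwise deletion). A query farther than `genusCutoff` from
#' every reference is gated out as `not_in_genus` (by default 0.05,
#' mirroring a 95% similarity retrieval threshold); when the two nearest
#' references of *different* species lie within `tieEpsilon` of each
#' other, the call is `ambiguous` and no species is assigned. Otherwise
#' the query is `concordant` when the assignment matches its given label
#' and `mislabeled` when it does not. Queries that are themselves panel
#' members are classified like any other sequence (at distance zero to
#' themselves).
#'
#' @param alignment a [BarcodeAlignment-class] holding the queries (and
#'   the panel rows, in the same coordinates).
#' @param labels the companion [SpeciesLabelMap-class] (given labels).
#' @param panel a `"ReferencePanel"` from [buildReferencePanel()].
#' @param genusCutoff genus-membership gate as a proportion
#'   (default `0.05`).
#' @param tieEpsilon tie tolerance between the best references of two
#'   species (default `0`, exact ties only).
#' @param queries ids to classify (default: all alignment ids).
#' @return a `data.frame` with columns `id`, `given`, `assigned`
#'   (`NA` for `not_in_genus`/`ambiguous`), `dMin`, `status`,
#'   `runnerUpSpecies`, `runnerUpDist`.
#' @export
classifySequences <- function(alignment, labels, panel,
    genusCutoff = 0.05, tieEpsilon = 0, queries = NULL) {
  stopifnot(is(alignment, "BarcodeAlignment"), is(labels, "SpeciesLabelMap"),
    inherits(panel, "ReferencePanel"))
  ids <- seqIds(alignment)
  if (is.null(queries)) queries <- ids
  bad <- setdiff(queries, ids)
  if (length(bad)) stop(sprintf("unknown query id: %s", bad[1L]))
  ld <- labelData(labels)
  given <- setNames(ld$species, ld$id)
  E <- .encodeACGTMatrix(alignmentMatrix(alignment))
  rows <- lapply(queries, function(q) {
    .classifyOne(q, E[match(q, ids), ], given[[q]], panel,
      genusCutoff, tieEpsilon)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

.classifyOne <- function(id, enc, givenLabel, panel, genusCutoff,
    tieEpsilon) {
  P <- panel$enc
  dists <- vapply(seq_len(nrow(P)), function(r) {
    ok <- !is.na(enc) & !is.na(P[r, ])
    n <- sum(ok)
    if (n == 0L) NA_real_ else sum(enc[ok] != P[r, ok]) / n
  }, numeric(1L))
  if (all(is.na(dists))) {
    stop(sprintf("no comparable sites between query '%s' and any reference",
      id))
  }
  perSpecies <- tapply(dists, panel$table$species, min, na.rm = TRUE)
  perSpecies <- perSpecies[is.finite(perSpecies)]
  ## deterministic order: distance, then species name (panel-order invariant)
  ord <- order(perSpecies, names(perSpecies))
  best <- perSpecies[ord[1L]]
  bestSp <- names(perSpecies)[ord[1L]]
  runnerUp <- if (length(ord) > 1L) {
    c(species = names(perSpecies)[ord[2L]],
      dist = unname(perSpecies[ord[2L]]))
  } else NULL
  dMin <- unname(best)
  tie <- length(ord) > 1L &&
    (perSpecies[ord[2L]] - best) <= tieEpsilon
  if (dMin > genusCutoff) {
    status <- "not_in_genus"; assigned <- NA_character_
  } else if (tie) {
    status <- "ambiguous"; assigned <- NA_character_
  } else if (!identical(bestSp, givenLabel)) {
    status <- "mislabeled"; assigned <- bestSp
  } else {
    status <- "concordant"; assigned <- bestSp
  }
  data.frame(id = id, given = givenLabel, assigned = assigned, dMin = dMin,
    status = status,
    runnerUpSpecies = if (is.null(runnerUp)) NA_character_ else
      runnerUp[["species"]],
    runnerUpDist = if (is.null(runnerUp)) NA_real_ else
      as.numeric(runnerUp[["dist"]]),
    stringsAsFactors = FALSE)
}

#' Mislabel report
#'
#' Tallies classification statuses split by material type (specimen vs
#' strain) and lists per-query corrections (given label to assigned
#' species) for the mislabeled records, the reporting shape used in
#' reference-sequence curation studies. Counts are reported separately and
#' never summed across categories.
#'
#' @param results a `data.frame` from [classifySequences()].
#' @param labels the [SpeciesLabelMap-class] providing material types.
#' @return a list with `counts` (`data.frame`: `material`, `status`, `n`,
#'   `nTotal`), `corrections` (`data.frame`: `id`, `material`, `given`,
#'   `assigned`, `dMin`) and `nQueries`.
#' @export
mislabelReport <- function(results, labels) {
  stopifnot(is.data.frame(results), is(labels, "SpeciesLabelMap"))
  ld <- labelData(labels)
  material <- setNames(ld$material, ld$id)[results$id]
  statuses <- c("concordant", "mislabeled", "not_in_genus", "ambiguous")
  materials <- c("specimen", "strain")
  counts <- expand.grid(material = materials, status = statuses,
    stringsAsFactors = FALSE)
  counts$n <- mapply(function(m, s) {
    sum(material == m & results$status == s, na.rm = TRUE)
  }, counts$material, counts$status)
  counts$nTotal <- vapply(counts$material,
    function(m) sum(material == m, na.rm = TRUE), integer(1L))
  mis <- results$status == "mislabeled"
  corrections <- data.frame(
    id = results$id[mis],
    material = unname(material[mis]),
    given = results$given[mis],
    assigned = results$assigned[mis],
    dMin = results$dMin[mis],
    stringsAsFactors = FALSE)
  list(counts = counts, corrections = corrections,
    nQueries = nrow(results))
}

#' Write classification results and mislabel report
#'
#' @param results a `data.frame` from [classifySequences()].
#' @param report a list from [mislabelReport()].
#' @param tsvPath path for the per-query classification TSV (distance as
#'   percentage) or `NULL`.
#' @param jsonPath path for the report JSON or `NULL`.
#' @return `results`, invisibly.
#' @export
writeClassification <- function(results, report = NULL, tsvPath = NULL,
    jsonPath = NULL) {
  if (!is.null(tsvPath)) {
    out <- data.frame(
      id = results$id, given = results$given, assigned = results$assigned,
      d_min_pct = formatPercent(results$dMin), status = results$status,
      runner_up = results$runnerUpSpecies,
      runner_up_pct = formatPercent(results$runnerUpDist))
    write.table(out, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE,
      na = "NA")
  }
  if (!is.null(jsonPath) && !is.null(report)) {
    jsonlite::write_json(list(
      n_queries = report$nQueries,
      counts = report$counts,
      corrections = report$corrections
    ), jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(results)
}
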