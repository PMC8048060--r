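#' Within-species distance ranges
#'
#' Collapses a pairwise distance matrix by species label: for every
#' species with at least two members, the minimum and maximum p-distance
#' over all defined intra-species pairs. Species represented by a single
#' sequence are excluded from the within-species analysis and listed
#' separately; undefined pairs (no comparable sites) are skipped with a
#' logged count.
#'
#' @param pdm a [PDistanceMatrix-class].
#' @param labels a [SpeciesLabelMap-class] covering the matrix ids.
#' @param quiet suppress log messages.
#' @return a list with `ranges` (a `data.frame`: `species`, `min`, `max`,
#'   `nPairs`) and `excludedSingletons` (character vector). Species whose
#'   intra-species pairs are all undefined keep a row with `NA` range and
#'   `nPairs = 0`.
#' @export
withinSpeciesRanges <- function(pdm, labels, quiet = FALSE) {
  stopifnot(is(pdm, "PDistanceMatrix"), is(labels, "SpeciesLabelMap"))
  sp <- .speciesOf(pdm, labels)
  d <- distValues(pdm)
  species <- sort(unique(sp))
  singles <- character()
  rows <- list()
  nUndef <- 0L
  for (s in species) {
    members <- which(sp == s)
    if (length(members) < 2L) {
      singles <- c(singles, s)
      next
    }
    pairs <- combn(members, 2L)
    vals <- d[cbind(pairs[1L, ], pairs[2L, ])]
    nUndef <- nUndef + sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    rows[[s]] <- data.frame(species = s,
      min = if (length(vals)) min(vals) else NA_real_,
      max = if (length(vals)) max(vals) else NA_real_,
      nPairs = length(vals), stringsAsFactors = FALSE)
  }
  if (nUndef > 0L) {
    .msg(quiet, sprintf("withinSpeciesRanges: skipped %d undefined pair(s)",
      nUndef))
  }
  ranges <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(species = character(), min = numeric(),
      max = numeric(), nPairs = integer())
  list(ranges = ranges, excludedSingletons = singles)
}

#' Between-species distance ranges
#'
#' For every unordered pair of species, the minimum and maximum p-distance
#' over all defined cross-species sequence pairs. A species pair with no
#' defined cross distance keeps a row with `NA` range (`"no data"`).
#'
#' @inheritParams withinSpeciesRanges
#' @return a `data.frame` with columns `species_i`, `species_j`, `min`,
#'   `max`, `nPairs`.
#' @export
betweenSpeciesRanges <- function(pdm, labels, quiet = FALSE) {
  stopifnot(is(pdm, "PDistanceMatrix"), is(labels, "SpeciesLabelMap"))
  sp <- .speciesOf(pdm, labels)
  species <- sort(unique(sp))
  if (length(species) < 2L) {
    stop("need at least 2 species for between-species ranges")
  }
  d <- distValues(pdm)
  rows <- list()
  nUndef <- 0L
  for (a in seq_len(length(species) - 1L)) {
    for (b in (a + 1L):length(species)) {
      vals <- d[sp == species[a], sp == species[b], drop = FALSE]
      nUndef <- nUndef + sum(is.na(vals))
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        species_i = species[a], species_j = species[b],
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_,
        nPairs = length(vals), stringsAsFactors = FALSE)
    }
  }
  if (nUndef > 0L) {
    .msg(quiet, sprintf("betweenSpeciesRanges: skipped %d undefined pair(s)",
      nUndef))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

.speciesOf <- function(pdm, labels) {
  ld <- labelData(labels)
  sp <- setNames(ld$species, ld$id)[seqIds(pdm)]
  if (anyNA(sp)) {
    stop(sprintf("no species label for id: %s",
      seqIds(pdm)[is.na(sp)][1L]))
  }
  unname(sp)
}

#' Estimate the barcoding-gap cut-off
#'
#' The cut-off is the largest observed within-species distance across
#' species not explicitly excluded; a clean barcoding gap (`gapOk`) exists
#' when every between-species minimum strictly exceeds the cut-off.
#' Species pairs whose between-species minimum falls below the cut-off are
#' reported as exceptions. High intra-species-variance species can be set
#' aside via `excludeSpecies` so the cut-off reflects the well-behaved
#' core of the genus; outlier detection is deliberately left to the
#' analyst.
#'
#' @param within result of [withinSpeciesRanges()] (the list or its
#'   `ranges` component).
#' @param between result of [betweenSpeciesRanges()].
#' @param excludeSpecies species names whose within ranges are ignored
#'   when taking the maximum (default none).
#' @param quiet suppress log messages.
#' @return a list with `cutoff` (proportion), `gapOk` (logical) and
#'   `exceptions` (`data.frame` of species pairs with `min` below the
#'   cut-off).
#' @export
estimateCutoff <- function(within, between, excludeSpecies = character(),
    quiet = FALSE) {
  ranges <- if (is.data.frame(within)) within else within$ranges
  pool <- ranges[!(ranges$species %in% excludeSpecies) & !is.na(ranges$max),
    , drop = FALSE]
  if (nrow(pool) == 0L) {
    stop("no within-species data after exclusions")
  }
  cutoff <- max(pool$max)
  .msg(quiet, sprintf("estimateCutoff: cutoff %s%% set by %s",
    formatPercent(cutoff), pool$species[which.max(pool$max)]))
  bmin <- between$min
  defined <- !is.na(bmin)
  gapOk <- all(defined) && all(bmin > cutoff)
  if (any(!defined)) {
    .msg(quiet, sprintf("estimateCutoff: %d species pair(s) with no data",
      sum(!defined)))
    gapOk <- all(bmin[defined] > cutoff)
  }
  exceptions <- between[defined & bmin < cutoff,
    c("species_i", "species_j", "min"), drop = FALSE]
  rownames(exceptions) <- NULL
  list(cutoff = cutoff, gapOk = gapOk, exceptions = exceptions)
}

#' Species-level distance summary
#'
#' Convenience wrapper running [withinSpeciesRanges()],
#' [betweenSpeciesRanges()] and [estimateCutoff()] in one call.
#'
#' @inheritParams withinSpeciesRanges
#' @inheritParams estimateCutoff
#' @return a list with components `within`, `excludedSingletons`,
#'   `between`, `cutoff`, `gapOk`, `exceptions`.
#' @export
speciesDistanceSummary <- function(pdm, labels,
    excludeSpecies = character(), quiet = FALSE) {
  w <- withinSpeciesRanges(pdm, labels, quiet = quiet)
  b <- betweenSpeciesRanges(pdm, labels, quiet = quiet)
  cut <- estimateCutoff(w, b, excludeSpecies = excludeSpecies, quiet = quiet)
  list(within = w$ranges, excludedSingletons = w$excludedSingletons,
    between = b, cutoff = cut$cutoff, gapOk = cut$gapOk,
    exceptions = cut$exceptions)
}

#' Write a species distance summary
#'
#' Writes a TSV with one block of within-species ranges and one block of
#' between-species ranges (distinguished by a `comparison` column, ranges
#' as percentages with two decimals), and optionally a JSON file with the
#' cut-off, gap verdict and exceptions.
#'
#' @param summary result of [speciesDistanceSummary()].
#' @param tsvPath path for the TSV output (or `NULL` to skip).
#' @param jsonPath path for the JSON output (or `NULL` to skip).
#' @return `summary`, invisibly.
#' @export
writeSpeciesSummary <- function(summary, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath)) {
    w <- summary$within
    b <- summary$between
    tab <- rbind(
      data.frame(comparison = "within", species_i = w$species,
        species_j = NA_character_, min_pct = formatPercent(w$min),
        max_pct = formatPercent(w$max), n_pairs = w$nPairs),
      data.frame(comparison = "between", species_i = b$species_i,
        species_j = b$species_j, min_pct = formatPercent(b$min),
        max_pct = formatPercent(b$max), n_pairs = b$nPairs)
    )
    write.table(tab, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE,
      na = "NA")
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(
      cutoff = summary$cutoff,
      cutoff_pct = as.numeric(formatPercent(summary$cutoff)),
      gap_ok = summary$gapOk,
      excluded_singletons = summary$excludedSingletons,
      exceptions = summary$exceptions
    ), jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(summary)
}
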