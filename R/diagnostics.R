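#' Per-species column profiles
#'
#' For each species and alignment column, collects the set of unambiguous
#' bases observed among that species' members. IUPAC ambiguity codes are
#' expanded to their base sets (`W` contributes `{A,T}`, `N` all four);
#' gaps contribute nothing but are counted. Intra-species variation at a
#' column is therefore captured as a multi-base residue set.
#'
#' @param alignment a [BarcodeAlignment-class].
#' @param labels the companion [SpeciesLabelMap-class].
#' @param species species to profile (default: all species in `labels`
#'   that have members among the alignment ids). A species with no member
#'   is an error.
#' @return a [ColumnProfiles-class].
#' @export
columnProfiles <- function(alignment, labels, species = NULL) {
  stopifnot(is(alignment, "BarcodeAlignment"), is(labels, "SpeciesLabelMap"))
  ld <- labelData(labels)
  spOf <- setNames(ld$species, ld$id)
  ids <- seqIds(alignment)
  if (is.null(species)) species <- sort(unique(unname(spOf[ids])))
  M <- alignmentMatrix(alignment)
  L <- ncol(M)
  codes <- matrix(0L, nrow = length(species), ncol = L,
    dimnames = list(species, NULL))
  gaps <- matrix(0L, nrow = length(species), ncol = L,
    dimnames = list(species, NULL))
  members <- integer(length(species))
  names(members) <- species
  for (s in species) {
    mids <- ids[!is.na(spOf[ids]) & spOf[ids] == s]
    if (length(mids) == 0L) {
      stop(sprintf("species '%s' has no members in the alignment", s))
    }
    members[s] <- length(mids)
    sub <- M[mids, , drop = FALSE]
    code <- rep(0L, L)
    for (r in seq_len(nrow(sub))) {
      code <- bitwOr(code, .IUPAC_BITS[sub[r, ]])
    }
    codes[s, ] <- code
    gaps[s, ] <- as.integer(colSums(sub == "-"))
  }
  new("ColumnProfiles", species = species, codes = codes, gapCounts = gaps,
    memberCounts = members)
}

#' IUPAC consensus sequence of a species
#'
#' The per-column consensus of a species over its residue set: the minimal
#' IUPAC symbol whose base set equals the observed set (`{A,T}` gives `W`,
#' all four give `N`), or `-` where every member is gapped. Columns where
#' some but not all members are gapped still yield the residue-set symbol;
#' gap presence is recorded separately in the profiles.
#'
#' @param profiles a [ColumnProfiles-class].
#' @param species a species name present in `profiles`.
#' @param columns columns to return (default: all).
#' @return character vector of IUPAC symbols/gaps, one per column.
#' @export
speciesConsensus <- function(profiles, species, columns = NULL) {
  stopifnot(is(profiles, "ColumnProfiles"))
  if (!species %in% profiles@species) {
    stop(sprintf("species '%s' not profiled", species))
  }
  code <- profiles@codes[species, ]
  if (!is.null(columns)) code <- code[columns]
  .BITS_TO_CODE[code + 1L]
}

#' Species-diagnostic alignment columns
#'
#' A column is diagnostic for a target species when the species' residue
#' set there is non-empty and shares no base with the union of all other
#' profiled species' residue sets. A column where every other species is
#' entirely gapped is diagnostic (presence/absence in an indel region is
#' informative), and intra-species variation expressed as an ambiguity
#' code still qualifies as long as the whole set is exclusive.
#'
#' @param profiles a [ColumnProfiles-class] covering at least two species.
#' @param target the target species name.
#' @return sorted integer vector of 1-based diagnostic column indices.
#' @export
diagnosticColumns <- function(profiles, target) {
  stopifnot(is(profiles, "ColumnProfiles"))
  if (!target %in% profiles@species) {
    stop(sprintf("target species '%s' not profiled", target))
  }
  if (length(profiles@species) < 2L) {
    stop("need at least 2 profiled species to call diagnostic columns")
  }
  own <- profiles@codes[target, ]
  others <- profiles@codes[setdiff(profiles@species, target), ,
    drop = FALSE]
  union <- rep(0L, ncol(others))
  for (r in seq_len(nrow(others))) union <- bitwOr(union, others[r, ])
  which(own != 0L & bitwAnd(own, union) == 0L)
}

#' Assemble diagnostic fragments for one species
#'
#' Merges diagnostic columns into candidate probe fragments by a greedy
#' left-to-right scan: consecutive diagnostic columns join the same
#' fragment when separated by at most `mergeGap` intervening columns.
#' Fragments are trimmed so both ends are diagnostic, and fragments with
#' fewer than `minDiag` diagnostic columns are discarded (a single
#' diagnostic site is not enough for a probe). The fragment sequence is
#' the species consensus over the span, skipping columns where the species
#' is entirely gapped - so a span may be longer than its sequence.
#'
#' @param profiles a [ColumnProfiles-class].
#' @param target the target species.
#' @param minDiag minimum diagnostic columns per fragment (>= 2).
#' @param mergeGap maximum intervening non-diagnostic columns joined into
#'   one fragment (default 5).
#' @return a `data.frame` with columns `species`, `sequence`, `start`,
#'   `end`, `nDiagnostic`, sorted by `start`; zero rows when no fragment
#'   qualifies.
#' @export
assembleFragments <- function(profiles, target, minDiag = 2L,
    mergeGap = 5L) {
  if (minDiag < 2L) stop("minDiag must be at least 2")
  if (mergeGap < 0L) stop("mergeGap must be non-negative")
  dcols <- diagnosticColumns(profiles, target)
  empty <- data.frame(species = character(), sequence = character(),
    start = integer(), end = integer(), nDiagnostic = integer())
  if (length(dcols) == 0L) return(empty)
  grp <- cumsum(c(0L, diff(dcols) - 1L > mergeGap))
  cons <- speciesConsensus(profiles, target)
  rows <- lapply(split(dcols, grp), function(cols) {
    if (length(cols) < minDiag) return(NULL)
    span <- cols[1L]:cols[length(cols)]
    piece <- cons[span]
    data.frame(species = target,
      sequence = paste(piece[piece != "-"], collapse = ""),
      start = cols[1L], end = cols[length(cols)],
      nDiagnostic = length(cols), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$start), , drop = FALSE]
}

#' Diagnostic fragments for a set of species
#'
#' Runs [columnProfiles()] and [assembleFragments()] for each species in
#' a chosen set (each species' columns judged against the *other species
#' of the set*), and returns the combined table sorted by alignment start
#' with joint letter labels, the layout of published diagnostic-sequence
#' tables.
#'
#' @inheritParams columnProfiles
#' @inheritParams assembleFragments
#' @param species the species set to analyse (default: all labelled
#'   species). At least two.
#' @return a `data.frame` with columns `label`, `species`, `sequence`,
#'   `start`, `end`, `nDiagnostic`.
#' @export
diagnosticFragments <- function(alignment, labels, species = NULL,
    minDiag = 2L, mergeGap = 5L) {
  profiles <- columnProfiles(alignment, labels, species = species)
  frames <- lapply(profiles@species, function(s) {
    assembleFragments(profiles, s, minDiag = minDiag, mergeGap = mergeGap)
  })
  out <- do.call(rbind, c(frames, make.row.names = FALSE))
  out <- out[order(out$start, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(label = .fragmentLabels(nrow(out)), out,
    stringsAsFactors = FALSE)
  out
}
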