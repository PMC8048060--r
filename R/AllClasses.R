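#' Multiple alignment of ITS barcode sequences
#'
#' A thin S4 wrapper around a [Biostrings::DNAStringSet] that enforces the
#' invariants every downstream module relies on: all rows have identical
#' length, identifiers are unique and non-empty, and residues are uppercase
#' IUPAC DNA symbols or the gap `-`. Column coordinates are 1-based and
#' inclusive throughout the package.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width sequences.
#' @seealso [readAlignedFasta()], [seqIds()], [nColumns()],
#'   [alignmentMatrix()]
#' @export
setClass("BarcodeAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("BarcodeAlignment", function(object) {
  s <- object@seqs
  if (length(s) == 0L) return("alignment contains no sequences")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) {
    return("every sequence must carry a non-empty identifier")
  }
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  }
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != w[1L]][1L]
    return(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
      bad, w[ids == bad][1L], w[1L]))
  }
  if (w[1L] == 0L) return("alignment has zero columns")
  TRUE
})

#' Construct a BarcodeAlignment
#'
#' @param seqs a named character vector of equal-length aligned sequences,
#'   or a [Biostrings::DNAStringSet]. Lowercase letters and `U` are
#'   normalised (`u`/`U` to `T`).
#' @return a [BarcodeAlignment-class] object.
#' @examples
#' aln <- BarcodeAlignment(c(a = "ACGT", b = "AC-T"))
#' nColumns(aln)
#' @export
BarcodeAlignment <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
    .checkResidues(seqs)
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  new("BarcodeAlignment", seqs = seqs)
}

## residue validation with id and column in the error message
.checkResidues <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% .ALPHABET))
    if (length(bad)) {
      stop(sprintf(
        "illegal character '%s' in sequence '%s' at column %d",
        ch[bad[1L]], ids[i], bad[1L]))
    }
  }
  invisible(TRUE)
}

#' Species labels, material types and reliability flags
#'
#' Per-sequence metadata mirroring a curated accession table: the species
#' name under which a record is filed, whether the material is a voucher
#' specimen or a cultured strain, and whether the sequence is considered a
#' reliable (expert-verified) record. Optional columns hold the accession,
#' host and geographic origin.
#'
#' @slot data a [S4Vectors::DataFrame] with columns `id`, `species`,
#'   `material` (`"specimen"` or `"strain"`), `reliable` (logical), and
#'   optionally `accession`, `host`, `origin`.
#' @seealso [readSpeciesLabels()], [labelData()]
#' @export
setClass("SpeciesLabelMap", slots = c(data = "DataFrame"))

setValidity("SpeciesLabelMap", function(object) {
  d <- object@data
  need <- c("id", "species", "material", "reliable")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) {
    return(paste("missing label columns:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(d$id)) {
    return(sprintf("duplicate id in label table: %s",
      d$id[duplicated(d$id)][1L]))
  }
  if (any(is.na(d$species) | !nzchar(d$species))) {
    return("species_label must be non-empty for every id")
  }
  bad <- setdiff(unique(d$material), c("specimen", "strain"))
  if (length(bad)) {
    return(sprintf("invalid material '%s': must be 'specimen' or 'strain'",
      bad[1L]))
  }
  if (!is.logical(d$reliable) || anyNA(d$reliable)) {
    return("reliable must be TRUE/FALSE with no missing values")
  }
  TRUE
})

#' Construct a SpeciesLabelMap
#'
#' @param data a `data.frame` or `DataFrame` with columns `id`, `species`,
#'   `material`, `reliable` (and optionally `accession`, `host`, `origin`).
#' @return a [SpeciesLabelMap-class] object.
#' @export
SpeciesLabelMap <- function(data) {
  d <- S4Vectors::DataFrame(data)
  for (opt in c("accession", "host", "origin")) {
    if (!opt %in% colnames(d)) d[[opt]] <- NA_character_
  }
  d$id <- as.character(d$id)
  d$species <- as.character(d$species)
  d$material <- as.character(d$material)
  new("SpeciesLabelMap", data = d)
}

#' Pairwise p-distance matrix with compared-site counts
#'
#' Symmetric matrix of uncorrected p-distances under pairwise deletion,
#' together with the number of compared sites per pair and (optionally)
#' site-bootstrap standard errors. A pair with no comparable sites has an
#' undefined (`NA`) distance and `nSites = 0`; undefined entries are always
#' flagged, never silently zero.
#'
#' @slot ids sequence identifiers (row/column order).
#' @slot d numeric matrix of distances in `[0, 1]`, `NA` where undefined.
#' @slot nSites integer matrix of compared-site counts.
#' @slot se numeric matrix of bootstrap standard errors (`NA` when not
#'   computed).
#' @seealso [pDistanceMatrix()], [distValues()], [siteCounts()]
#' @export
setClass("PDistanceMatrix",
  slots = c(ids = "character", d = "matrix", nSites = "matrix",
    se = "matrix"))

setValidity("PDistanceMatrix", function(object) {
  n <- length(object@ids)
  d <- object@d; ns <- object@nSites
  if (!all(dim(d) == n) || !all(dim(ns) == n) || !all(dim(object@se) == n)) {
    return("matrix dimensions must match the number of ids")
  }
  if (!isTRUE(all.equal(d, t(d)))) return("distance matrix must be symmetric")
  if (!identical(ns, t(ns))) return("site-count matrix must be symmetric")
  if (any(!is.na(d) & (d < 0 | d > 1))) return("distances must lie in [0, 1]")
  und <- is.na(d)
  if (!identical(und, ns == 0L)) {
    return("distance undefined iff nSites == 0 violated")
  }
  if (any(!is.na(diag(d)) & diag(d) != 0)) {
    return("defined diagonal entries must be zero")
  }
  TRUE
})

#' Per-species, per-column residue profiles
#'
#' For each species and alignment column, the set of unambiguous bases
#' observed among the species' members (IUPAC ambiguity codes expanded to
#' their base sets, e.g. `W` contributes `{A,T}`), stored as a 4-bit mask,
#' plus the count of gapped members. The residue set is empty only when all
#' members are gapped at that column.
#'
#' @slot species species names (row order of the matrices).
#' @slot codes integer matrix (species x columns) of residue-set bit masks.
#' @slot gapCounts integer matrix (species x columns) of gapped members.
#' @slot memberCounts named integer vector of members per species.
#' @seealso [columnProfiles()], [speciesConsensus()], [diagnosticColumns()]
#' @export
setClass("ColumnProfiles",
  slots = c(species = "character", codes = "matrix", gapCounts = "matrix",
    memberCounts = "integer"))

setValidity("ColumnProfiles", function(object) {
  k <- length(object@species)
  if (nrow(object@codes) != k || nrow(object@gapCounts) != k) {
    return("profile matrices must have one row per species")
  }
  if (!identical(dim(object@codes), dim(object@gapCounts))) {
    return("codes and gapCounts must share dimensions")
  }
  ## empty residue set only when every member is gapped
  full <- object@memberCounts[object@species]
  emptyOk <- object@codes != 0L | object@gapCounts == matrix(full,
    nrow = k, ncol = ncol(object@codes))
  if (!all(emptyOk)) {
    return("empty residue set at a column where not all members are gapped")
  }
  TRUE
})

setMethod("show", "BarcodeAlignment", function(object) {
  cat(sprintf("BarcodeAlignment: %d sequences x %d columns\n",
    length(object@seqs), nColumns(object)))
  ids <- names(object@seqs)
  shown <- utils::head(ids, 5L)
  cat("  ids:", paste(shown, collapse = ", "),
    if (length(ids) > 5L) sprintf("... (%d more)", length(ids) - 5L) else "",
    "\n")
})

setMethod("show", "SpeciesLabelMap", function(object) {
  d <- object@data
  cat(sprintf("SpeciesLabelMap: %d records, %d species\n",
    nrow(d), length(unique(d$species))))
  cat(sprintf("  material: %d specimen / %d strain; %d reliable\n",
    sum(d$material == "specimen"), sum(d$material == "strain"),
    sum(d$reliable)))
})

setMethod("show", "PDistanceMatrix", function(object) {
  n <- length(object@ids)
  off <- object@d[upper.tri(object@d)]
  cat(sprintf("PDistanceMatrix: %d sequences (%d pairs, %d undefined)\n",
    n, length(off), sum(is.na(off))))
  if (any(!is.na(off))) {
    cat(sprintf("  p-distance range: %s%% - %s%%\n",
      formatPercent(min(off, na.rm = TRUE)),
      formatPercent(max(off, na.rm = TRUE))))
  }
})

setMethod("show", "ColumnProfiles", function(object) {
  cat(sprintf("ColumnProfiles: %d species x %d columns\n",
    length(object@species), ncol(object@codes)))
})
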