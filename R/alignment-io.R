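#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format and validates it:
#' all rows must have identical length and contain only IUPAC DNA symbols
#' or the gap character `-` after normalisation. Lowercase input is
#' uppercased and `U` is converted to `T`, since public ITS records vary in
#' both respects. Identifiers are taken as the first whitespace-delimited
#' token of each header line.
#'
#' @param path path to an aligned FASTA file.
#' @return a [BarcodeAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "AC-T"), fa)
#' readAlignedFasta(fa)
#' @export
readAlignedFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop(sprintf("no sequences in %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id in FASTA: %s",
      ids[duplicated(ids)][1L]))
  }
  seqs <- as.character(raw)
  names(seqs) <- ids
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != w[1L]][1L]
    stop(sprintf(
      "ragged alignment: sequence '%s' has length %d, expected %d",
      bad, w[names(seqs) == bad][1L], w[1L]))
  }
  BarcodeAlignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param alignment a [BarcodeAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(alignment, path) {
  stopifnot(is(alignment, "BarcodeAlignment"))
  Biostrings::writeXStringSet(alignment@seqs, filepath = path)
  invisible(path)
}

#' Read a species-label table
#'
#' Reads a tab-delimited table with a header and at least the columns `id`,
#' `species`, `material` and `reliable` (optionally `accession`, `host`,
#' `origin`), and checks it against a companion alignment. In strict mode
#' (the default) the table ids and the alignment ids must match exactly; in
#' loose mode unmatched table rows are dropped with a warning and alignment
#' ids without labels are reported.
#'
#' @param path path to the TSV file.
#' @param alignment the companion [BarcodeAlignment-class].
#' @param strict logical; enforce exact id matching (default `TRUE`).
#' @return a [SpeciesLabelMap-class] with one record per alignment id
#'   (strict mode) or per matched id (loose mode).
#' @export
readSpeciesLabels <- function(path, alignment, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  stopifnot(is(alignment, "BarcodeAlignment"))
  d <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  need <- c("id", "species", "material", "reliable")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) {
    stop(paste("label table missing columns:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(d$id)) {
    stop(sprintf("duplicate id in label table: %s",
      d$id[duplicated(d$id)][1L]))
  }
  d$reliable <- .parseBoolean(d$reliable, "reliable")
  alnIds <- seqIds(alignment)
  extra <- setdiff(d$id, alnIds)
  absent <- setdiff(alnIds, d$id)
  if (strict) {
    if (length(extra)) {
      stop(sprintf("label id absent from alignment: %s", extra[1L]))
    }
    if (length(absent)) {
      stop(sprintf("alignment id missing from label table: %s", absent[1L]))
    }
  } else {
    if (length(extra)) {
      warning(sprintf("dropping %d label row(s) not in alignment: %s",
        length(extra), paste(head(extra, 5L), collapse = ", ")))
      d <- d[d$id %in% alnIds, , drop = FALSE]
    }
    if (length(absent)) {
      warning(sprintf("%d alignment id(s) have no label: %s",
        length(absent), paste(head(absent, 5L), collapse = ", ")))
    }
  }
  ## keep alignment order for the ids we have
  d <- d[order(match(d$id, alnIds)), , drop = FALSE]
  SpeciesLabelMap(d)
}

.parseBoolean <- function(x, what) {
  v <- rep(NA, length(x))
  v[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  v[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(v)) {
    stop(sprintf("cannot parse %s value '%s' as boolean",
      what, x[is.na(v)][1L]))
  }
  v
}

#' Read reference-sequence designations
#'
#' A designation names, for each species, one or more sequence ids that
#' serve as its reliable reference (from holotypes where possible). The
#' file is a TSV with header columns `species` and `id`.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with columns `species` and `id`.
#' @seealso [buildReferencePanel()]
#' @export
readReferenceDesignations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("species", "id"), colnames(d))
  if (length(miss)) {
    stop(paste("designation table missing columns:",
      paste(miss, collapse = ", ")))
  }
  d[, c("species", "id")]
}

#' Write a diagnostic-fragment table
#'
#' Writes fragments as a TSV with columns `label`, `species`, `sequence`,
#' `start`, `end`, `n_diagnostic`. Labels `A`, `B`, `C`, ... are assigned
#' across all species jointly in order of alignment start column, the
#' convention used for published diagnostic-fragment tables. An empty
#' fragment list yields a header-only file.
#'
#' @param fragments a `data.frame` as returned by [diagnosticFragments()]
#'   or [assembleFragments()] (columns `species`, `sequence`, `start`,
#'   `end`, `nDiagnostic`).
#' @param path output file path.
#' @return the labelled `data.frame`, invisibly.
#' @export
writeFragmentsTable <- function(fragments, path) {
  stopifnot(is.data.frame(fragments))
  out <- fragments[order(fragments$start, fragments$species), , drop = FALSE]
  out <- data.frame(
    label = .fragmentLabels(nrow(out)),
    species = out$species,
    sequence = out$sequence,
    start = out$start,
    end = out$end,
    n_diagnostic = out$nDiagnostic,
    stringsAsFactors = FALSE
  )
  if (nrow(fragments) == 0L) {
    out <- data.frame(label = character(), species = character(),
      sequence = character(), start = integer(), end = integer(),
      n_diagnostic = integer())
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a species-label table
#'
#' Inverse of [readSpeciesLabels()]; used by the simulator and pipeline.
#'
#' @param labels a [SpeciesLabelMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpeciesLabels <- function(labels, path) {
  stopifnot(is(labels, "SpeciesLabelMap"))
  d <- as.data.frame(labelData(labels))
  d$reliable <- ifelse(d$reliable, "true", "false")
  cols <- c("id", "accession", "species", "material", "reliable",
    "host", "origin")
  write.table(d[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  invisible(path)
}
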