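#' Pairwise p-distance under pairwise deletion
#'
#' The uncorrected p-distance between two aligned sequences: the proportion
#' of mismatching sites among compared sites. A column is compared only
#' when *both* residues are unambiguous bases (`A`, `C`, `G`, `T`); gaps
#' and all IUPAC ambiguity codes are treated as missing data and deleted
#' pairwise, matching the standard treatment for p-distances. Transitions
#' and transversions both count as mismatches.
#'
#' @param x,y aligned sequences of equal length, as single strings or
#'   character vectors of residues.
#' @return a list with elements `distance` (proportion in `[0, 1]`, or
#'   `NA` when no sites are comparable) and `nSites` (integer count of
#'   compared sites).
#' @examples
#' pairwisePDistance("AC-GT", "AAAGT") # column 3 deleted -> 0.25 over 4
#' pairwisePDistance("ACGT", "ACGY")   # ambiguity deleted -> 0 over 3
#' @export
pairwisePDistance <- function(x, y) {
  cx <- if (length(x) == 1L) .encodeACGT(x) else match(x, .BASES)
  cy <- if (length(y) == 1L) .encodeACGT(y) else match(y, .BASES)
  if (length(cx) != length(cy)) {
    stop("sequences must have equal aligned length")
  }
  ok <- !is.na(cx) & !is.na(cy)
  n <- sum(ok)
  if (n == 0L) {
    return(list(distance = NA_real_, nSites = 0L))
  }
  list(distance = sum(cx[ok] != cy[ok]) / n, nSites = n)
}

#' Full pairwise p-distance matrix
#'
#' Computes all pairwise p-distances of an alignment under pairwise
#' deletion (see [pairwisePDistance()]). The result is symmetric with a
#' zero diagonal; pairs with no comparable sites carry `NA` distances and
#' zero site counts. With `bootstrapReplicates > 0`, a site-bootstrap
#' standard error is computed for every pair (see [bootstrapSE()]).
#'
#' @param alignment a [BarcodeAlignment-class] with at least two rows.
#' @param bootstrapReplicates number of bootstrap replicates per pair
#'   (0 = skip; published analyses typically use 1000).
#' @param seed integer seed, required when `bootstrapReplicates > 0`.
#' @return a [PDistanceMatrix-class].
#' @examples
#' aln <- BarcodeAlignment(c(a = "ACGT", b = "ACGA", c = "TCGA"))
#' distValues(pDistanceMatrix(aln))
#' @export
pDistanceMatrix <- function(alignment, bootstrapReplicates = 0L,
    seed = NULL) {
  stopifnot(is(alignment, "BarcodeAlignment"))
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences for a distance matrix")
  E <- .encodeACGTMatrix(alignmentMatrix(alignment))
  ids <- seqIds(alignment)
  d <- matrix(0, n, n)
  ns <- matrix(0L, n, n)
  valid <- !is.na(E)
  for (i in seq_len(n)) {
    ns[i, i] <- sum(valid[i, ])
    if (ns[i, i] == 0L) d[i, i] <- NA_real_
    for (j in if (i < n) (i + 1L):n else integer()) {
      ok <- valid[i, ] & valid[j, ]
      m <- sum(ok)
      ns[i, j] <- ns[j, i] <- m
      d[i, j] <- d[j, i] <-
        if (m == 0L) NA_real_ else sum(E[i, ok] != E[j, ok]) / m
    }
  }
  se <- matrix(NA_real_, n, n)
  if (bootstrapReplicates > 0L) {
    if (is.null(seed)) stop("seed is required for bootstrap replication")
    set.seed(seed)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        se[i, j] <- se[j, i] <- .bootstrapSEPair(E[i, ], E[j, ],
          bootstrapReplicates)
      }
    }
  }
  new("PDistanceMatrix", ids = ids, d = d, nSites = ns, se = se)
}

#' Site-bootstrap standard error of a pairwise p-distance
#'
#' Resamples alignment columns with replacement (over the *full* alignment
#' length, not the pairwise-deleted subset), recomputes the p-distance of
#' the pair within each replicate with pairwise deletion applied afresh,
#' and returns the standard deviation of the replicate distances. This is
#' the site-resampling variance estimate conventionally reported alongside
#' barcode distances. Replicates in which the pair shares no comparable
#' site are excluded. Seeded runs are reproducible bit for bit.
#'
#' @param alignment a [BarcodeAlignment-class].
#' @param pair character vector of two sequence ids.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed (required).
#' @return the bootstrap standard error, or `NA` when the pair has no
#'   comparable sites.
#' @examples
#' aln <- BarcodeAlignment(c(a = "ACGT", b = "ACGA"))
#' bootstrapSE(aln, c("a", "b"), replicates = 1000, seed = 1)
#' @export
bootstrapSE <- function(alignment, pair, replicates = 1000L, seed) {
  stopifnot(is(alignment, "BarcodeAlignment"), length(pair) == 2L,
    replicates >= 1L)
  if (missing(seed)) stop("seed is required for bootstrap replication")
  ids <- seqIds(alignment)
  idx <- match(pair, ids)
  if (anyNA(idx)) {
    stop(sprintf("unknown sequence id: %s", pair[is.na(idx)][1L]))
  }
  M <- alignmentMatrix(alignment)
  set.seed(seed)
  .bootstrapSEPair(match(M[idx[1L], ], .BASES), match(M[idx[2L], ], .BASES),
    replicates)
}

## core: x, y are integer-coded rows (NA = missing); draws replicates via
## multinomial column counts, equivalent in distribution to resampling L
## columns with replacement
.bootstrapSEPair <- function(x, y, replicates) {
  L <- length(x)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  mism <- as.numeric(ok & x != y)
  mism[is.na(mism)] <- 0
  counts <- rmultinom(replicates, L, rep(1 / L, L))
  nv <- as.vector(crossprod(counts, as.numeric(ok)))
  nm <- as.vector(crossprod(counts, mism))
  reps <- ifelse(nv > 0, nm / nv, NA_real_)
  sd(reps, na.rm = TRUE)
}

#' Write a distance matrix to TSV
#'
#' Writes the square matrix (ids as header row and first column) and,
#' optionally, a long-format table with one row per unordered pair
#' (`id_i`, `id_j`, `distance`, `n_sites`, `se`).
#'
#' @param pdm a [PDistanceMatrix-class].
#' @param squarePath path for the square TSV (or `NULL` to skip).
#' @param longPath path for the long-format TSV (or `NULL` to skip).
#' @param percent logical; write distances (and SEs) as percentages with
#'   two decimals instead of proportions.
#' @return invisibly, the long-format `data.frame`.
#' @export
writeDistanceMatrix <- function(pdm, squarePath = NULL, longPath = NULL,
    percent = FALSE) {
  stopifnot(is(pdm, "PDistanceMatrix"))
  d <- distValues(pdm)
  if (!is.null(squarePath)) {
    sq <- if (percent) {
      matrix(formatPercent(d), nrow = nrow(d), dimnames = dimnames(d))
    } else d
    write.table(data.frame(id = rownames(sq), sq, check.names = FALSE),
      squarePath, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  ids <- seqIds(pdm)
  n <- length(ids)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  long <- data.frame(
    id_i = ids[ut[, "row"]],
    id_j = ids[ut[, "col"]],
    distance = d[ut],
    n_sites = siteCounts(pdm)[ut],
    se = bootstrapSEs(pdm)[ut],
    stringsAsFactors = FALSE
  )
  long <- long[order(match(long$id_i, ids), match(long$id_j, ids)), ]
  if (!is.null(longPath)) {
    out <- long
    if (percent) {
      out$distance <- formatPercent(out$distance)
      out$se <- formatPercent(out$se)
    }
    write.table(out, longPath, sep = "\t", quote = FALSE, row.names = FALSE,
      na = "NA")
  }
  invisible(long)
}
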