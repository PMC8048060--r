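#' @import methods
#' @importFrom stats rmultinom runif sd rpois setNames
#' @importFrom utils read.delim write.table combn packageVersion head
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

## Alphabet machinery shared by every module.
##
## Each IUPAC symbol is a 4-bit mask over (A, C, G, T) so that residue-set
## union is bitwOr() and residue-set intersection is bitwAnd(). The gap maps
## to the empty set (0).

.BASES <- c("A", "C", "G", "T")

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L,
  "-" = 0L
)

## inverse lookup: bit mask (0..15) -> minimal IUPAC symbol; index = mask + 1
.BITS_TO_CODE <- local({
  out <- character(16L)
  out[.IUPAC_BITS + 1L] <- names(.IUPAC_BITS)
  out
})

.ALPHABET <- names(.IUPAC_BITS)

## unambiguous-base codes for the distance engine: A,C,G,T -> 1..4, else NA
.ACGT_CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A") + 1L] <- 1L
  x[utf8ToInt("C") + 1L] <- 2L
  x[utf8ToInt("G") + 1L] <- 3L
  x[utf8ToInt("T") + 1L] <- 4L
  x
})

## encode one sequence string as integer codes (NA = gap/ambiguity/missing)
.encodeACGT <- function(s) {
  .ACGT_CODE[utf8ToInt(s) + 1L]
}

## encode a character matrix of residues (rows = sequences)
.encodeACGTMatrix <- function(m) {
  matrix(match(m, .BASES), nrow = nrow(m), dimnames = dimnames(m))
}

#' Format a proportion as a percentage string
#'
#' Distances are proportions internally; the reporting layer prints
#' percentages with two decimals (e.g. `0.0268` becomes `"2.68"`).
#'
#' @param p numeric vector of proportions.
#' @param digits number of decimal places.
#' @return character vector of formatted percentages (no `%` sign).
#' @export
formatPercent <- function(p, digits = 2L) {
  ifelse(is.na(p), NA_character_, sprintf(paste0("%.", digits, "f"), 100 * p))
}

.msg <- function(quiet, ...) {
  if (!isTRUE(quiet)) message(...)
}

## fragment labels: A..Z, then AA, AB, ... (Table-2 style lettering)
.fragmentLabels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, function(a, b) paste0(a, b))))[seq_len(n)]
}
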