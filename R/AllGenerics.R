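#' Sequence identifiers of an object
#' @param x a [BarcodeAlignment-class], [PDistanceMatrix-class] or
#'   [SpeciesLabelMap-class].
#' @return character vector of ids.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Number of alignment columns
#' @param x a [BarcodeAlignment-class].
#' @return integer, the alignment width.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' Alignment as a character matrix
#' @param x a [BarcodeAlignment-class].
#' @return character matrix, rows = sequences (named), columns = positions.
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Label table of a SpeciesLabelMap
#' @param x a [SpeciesLabelMap-class].
#' @return the underlying [S4Vectors::DataFrame].
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' Distance values of a PDistanceMatrix
#' @param x a [PDistanceMatrix-class].
#' @return symmetric numeric matrix of p-distances (`NA` = undefined).
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' Compared-site counts of a PDistanceMatrix
#' @param x a [PDistanceMatrix-class].
#' @return symmetric integer matrix of compared-site counts.
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))

#' Bootstrap standard errors of a PDistanceMatrix
#' @param x a [PDistanceMatrix-class].
#' @return symmetric numeric matrix of standard errors (`NA` when not
#'   computed).
#' @export
setGeneric("bootstrapSEs", function(x) standardGeneric("bootstrapSEs"))

#' @rdname seqIds
#' @export
setMethod("seqIds", "BarcodeAlignment", function(x) names(x@seqs))

#' @rdname seqIds
#' @export
setMethod("seqIds", "PDistanceMatrix", function(x) x@ids)

#' @rdname seqIds
#' @export
setMethod("seqIds", "SpeciesLabelMap", function(x) x@data$id)

#' @rdname nColumns
#' @export
setMethod("nColumns", "BarcodeAlignment",
  function(x) Biostrings::width(x@seqs)[1L])

#' @rdname alignmentMatrix
#' @export
setMethod("alignmentMatrix", "BarcodeAlignment",
  function(x) as.matrix(x@seqs))

#' @rdname labelData
#' @export
setMethod("labelData", "SpeciesLabelMap", function(x) x@data)

#' @rdname distValues
#' @export
setMethod("distValues", "PDistanceMatrix", function(x) {
  d <- x@d
  dimnames(d) <- list(x@ids, x@ids)
  d
})

#' @rdname siteCounts
#' @export
setMethod("siteCounts", "PDistanceMatrix", function(x) {
  m <- x@nSites
  dimnames(m) <- list(x@ids, x@ids)
  m
})

#' @rdname bootstrapSEs
#' @export
setMethod("bootstrapSEs", "PDistanceMatrix", function(x) {
  m <- x@se
  dimnames(m) <- list(x@ids, x@ids)
  m
})

#' Number of sequences in an alignment
#' @param x a [BarcodeAlignment-class].
#' @return integer.
#' @export
setMethod("length", "BarcodeAlignment", function(x) length(x@seqs))
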