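#' Simulate a species-structured barcode alignment
#'
#' Generates an alignment with known species structure so every pipeline
#' stage can be exercised against ground truth. A genus ancestor sequence
#' is drawn uniformly over the four bases; each species root mutates the
#' ancestor per site with probability `pInter` (new base uniform over the
#' other three); each member mutates its species root likewise with
#' `pIntra`. Optional indel blocks gap out contiguous columns of randomly
#' chosen species (exercising pairwise deletion and gap diagnostics);
#' planted fragments overwrite the target species' members at chosen
#' columns and force a different residue in every other species there, so
#' they are species-diagnostic by construction. Labels equal the truth,
#' after which a known fraction can be swapped to a wrong species.
#'
#' The defaults are the package's reference study conditions: 3 species of
#' 5 members over 600 columns with per-site intra-species divergence 0.005
#' and inter-species divergence 0.03.
#'
#' The first member of each species is marked reliable and designated as
#' the species' reference; injected mislabels never hit these designated
#' reference ids, so the reference panel itself stays clean (see
#' [injectMislabels()]).
#'
#' @param nSpecies number of species clusters.
#' @param membersPerSpecies members per species.
#' @param nColumns alignment length.
#' @param pIntra per-site member-vs-root substitution probability.
#' @param pInter per-site root-vs-ancestor substitution probability.
#' @param indelBlockRate expected number of gapped blocks per species
#'   (Poisson; block length 5-15 columns, all members of one species
#'   gapped). Default 0.
#' @param plantedFragments list of `list(species=, columns=, bases=)`
#'   entries; `bases` is a character vector (one base per column) or a
#'   single string.
#' @param mislabelFraction fraction of sequences whose label is swapped to
#'   a uniformly chosen different species.
#' @param seed integer seed (mandatory; the generator is fully
#'   reproducible from it).
#' @return a list with `alignment` ([BarcodeAlignment-class]), `labels`
#'   (the possibly mislabeled [SpeciesLabelMap-class]), `references`
#'   (`data.frame`: `species`, `id`) and `truth` (list: `trueSpecies`
#'   named character, `cleanLabels`, `swappedIds`, `ancestor`, `roots`,
#'   `plantedFragments`).
#' @examples
#' sim <- simulateBarcodeData(seed = 7)
#' sim$alignment
#' @export
simulateBarcodeData <- function(nSpecies = 3L, membersPerSpecies = 5L,
    nColumns = 600L, pIntra = 0.005, pInter = 0.03, indelBlockRate = 0,
    plantedFragments = list(), mislabelFraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory for the simulator")
  stopifnot(nSpecies >= 1L, membersPerSpecies >= 1L, nColumns >= 1L,
    pIntra >= 0, pIntra <= 1, pInter >= 0, pInter <= 1,
    indelBlockRate >= 0)
  if (mislabelFraction < 0 || mislabelFraction > 1) {
    stop("mislabelFraction must lie in [0, 1]")
  }
  set.seed(seed)
  speciesNames <- sprintf("Species%02d", seq_len(nSpecies))
  ancestor <- sample(.BASES, nColumns, replace = TRUE)
  roots <- lapply(seq_len(nSpecies), function(s) {
    .mutate(ancestor, pInter)
  })
  names(roots) <- speciesNames
  n <- nSpecies * membersPerSpecies
  M <- matrix("", nrow = n, ncol = nColumns)
  ids <- character(n)
  trueSpecies <- character(n)
  k <- 0L
  for (s in seq_len(nSpecies)) {
    for (m in seq_len(membersPerSpecies)) {
      k <- k + 1L
      ids[k] <- sprintf("seq_%02d_%02d", s, m)
      trueSpecies[k] <- speciesNames[s]
      M[k, ] <- .mutate(roots[[s]], pIntra)
    }
  }
  rownames(M) <- ids
  names(trueSpecies) <- ids
  ## planted species-unique fragments
  planted <- lapply(plantedFragments, function(f) {
    cols <- as.integer(f$columns)
    bases <- if (length(f$bases) == 1L && nchar(f$bases[1L]) > 1L) {
      strsplit(f$bases, "", fixed = TRUE)[[1L]]
    } else as.character(f$bases)
    if (length(bases) != length(cols)) {
      stop("planted fragment: bases and columns lengths differ")
    }
    if (any(cols < 1L | cols > nColumns)) {
      stop("planted fragment: columns outside alignment range")
    }
    if (!f$species %in% speciesNames) {
      stop(sprintf("planted fragment: unknown species '%s'", f$species))
    }
    list(species = f$species, columns = cols, bases = bases)
  })
  for (f in planted) {
    tgt <- trueSpecies == f$species
    for (i in seq_along(f$columns)) {
      M[tgt, f$columns[i]] <- f$bases[i]
      ## force every other species to a fixed different residue
      for (s in setdiff(speciesNames, f$species)) {
        alt <- sample(setdiff(.BASES, f$bases[i]), 1L)
        M[trueSpecies == s, f$columns[i]] <- alt
      }
    }
  }
  ## indel blocks: contiguous columns gapped in all members of one species
  nBlocks <- rpois(1L, indelBlockRate * nSpecies)
  for (b in seq_len(nBlocks)) {
    len <- sample(5:15, 1L)
    start <- sample.int(max(1L, nColumns - len + 1L), 1L)
    cols <- start:min(nColumns, start + len - 1L)
    sp <- sample(speciesNames, 1L)
    for (f in planted) {
      if (identical(f$species, sp) && length(intersect(cols, f$columns))) {
        stop(sprintf(
          "indel block (columns %d-%d) collides with planted fragment in %s",
          cols[1L], cols[length(cols)], sp))
      }
    }
    M[trueSpecies == sp, cols] <- "-"
  }
  material <- ifelse(runif(n) < 0.3, "specimen", "strain")
  refIdx <- match(speciesNames, trueSpecies) # first member of each species
  reliable <- seq_len(n) %in% refIdx
  cleanLabels <- SpeciesLabelMap(data.frame(
    id = ids, accession = NA_character_, species = unname(trueSpecies),
    material = material, reliable = reliable, stringsAsFactors = FALSE))
  references <- data.frame(species = speciesNames, id = ids[refIdx],
    stringsAsFactors = FALSE)
  inj <- injectMislabels(cleanLabels, mislabelFraction,
    seed = sample.int(.Machine$integer.max, 1L), exclude = references$id)
  alignment <- BarcodeAlignment(apply(M, 1L, paste, collapse = ""))
  list(alignment = alignment, labels = inj$labels,
    references = references,
    truth = list(trueSpecies = trueSpecies, cleanLabels = cleanLabels,
      swappedIds = inj$swappedIds, ancestor = paste(ancestor, collapse = ""),
      roots = vapply(roots, paste, character(1L), collapse = ""),
      plantedFragments = planted))
}

## per-site substitution to a uniformly chosen different base
.mutate <- function(seq, p) {
  hit <- which(runif(length(seq)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    seq[hit] <- .BASES[(match(seq[hit], .BASES) - 1L + shift) %% 4L + 1L]
  }
  seq
}

#' Inject mislabels into a label map
#'
#' Swaps the species label of `round(fraction * n)` sequences to a
#' uniformly chosen *different* species, recording which ids were swapped.
#' Ids listed in `exclude` (e.g. designated reference sequences) are never
#' swapped; the swap count is still computed from the full table size.
#'
#' @param labels a [SpeciesLabelMap-class] with at least two species.
#' @param fraction fraction of sequences to mislabel, in `[0, 1]`.
#' @param seed integer seed (mandatory).
#' @param exclude ids exempt from swapping.
#' @return a list with `labels` (the modified [SpeciesLabelMap-class]) and
#'   `swappedIds` (character vector).
#' @export
injectMislabels <- function(labels, fraction, seed, exclude = character()) {
  stopifnot(is(labels, "SpeciesLabelMap"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (missing(seed)) stop("seed is mandatory for mislabel injection")
  d <- as.data.frame(labelData(labels))
  speciesPool <- unique(d$species)
  k <- round(fraction * nrow(d))
  if (k == 0L) return(list(labels = labels, swappedIds = character()))
  if (length(speciesPool) < 2L) {
    stop("need at least 2 species to inject mislabels")
  }
  candidates <- setdiff(d$id, exclude)
  if (k > length(candidates)) {
    stop("not enough non-excluded sequences to mislabel")
  }
  set.seed(seed)
  swapped <- sample(candidates, k)
  for (id in swapped) {
    i <- match(id, d$id)
    d$species[i] <- sample(setdiff(speciesPool, d$species[i]), 1L)
  }
  list(labels = SpeciesLabelMap(d), swappedIds = swapped)
}
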