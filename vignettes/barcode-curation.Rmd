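---
title: "Curating ITS barcode reference sets: distances, gaps, mislabels and diagnostic fragments"
author: "barcodeGap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating ITS barcode reference sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeGap)
```

## The problem

The internal transcribed spacer (ITS) of the ribosomal cistron is the
standard DNA barcode for fungi, and for many genera of interest —
medicinal wood-inhabiting mushrooms are a notorious case — a large share
of the ITS records in public databases carry wrong species names. Most
of those records were deposited by non-taxonomists, and every
similarity-search identification against the polluted set mints new
errors. Cleaning up such a genus requires four quantitative steps, and
this package implements each of them on top of a fixed multiple
sequence alignment (producing the alignment itself, e.g. with MAFFT, is
out of scope — alignments are consumed as input):

1. pairwise genetic distances between all sequences;
2. a within- vs between-species summary of those distances and an
   identification cut-off (the "barcoding gap");
3. flagging of records whose label conflicts with their distance to
   designated reliable reference sequences;
4. discovery of short alignment regions unique to one species, the raw
   material for rapid diagnostic assays such as hyperbranched rolling
   circle amplification (HRCA).

## Distance model

For two rows of the alignment the package computes the uncorrected
*p*-distance: the proportion of differing sites among compared sites,
with transitions and transversions counted alike and no multiple-hit
correction. Sites are compared under **pairwise deletion**: a column
enters a pair's comparison only when *both* residues are unambiguous
bases `A/C/G/T`. Gaps *and* IUPAC ambiguity codes are treated as missing
data. The ambiguity rule deserves a note: distance tools vary here, and
treating ambiguity codes as missing (rather than as partial matches) is
the convention under which a species whose consensus carries ambiguity
elsewhere can still show a within-species distance of exactly 0.00%.
Distances are proportions internally; only the reporting layer prints
percentages (two decimals).

A pair sharing no comparable column has an *undefined* distance: it is
carried as a flagged missing value (`NA` with a zero site count), never
as a silent zero, and every summary skips undefined pairs with a logged
count.

Uniform rates across sites are assumed throughout; model-corrected
distances (JC, K2P, ...) are deliberately not offered — for the short,
closely related sequences this workflow targets, the uncorrected
proportion is the quantity practitioners tabulate and threshold.

### Bootstrap variance

`bootstrapSE()` estimates the sampling error of a pairwise distance by
site resampling: alignment columns are drawn with replacement over the
*full* alignment length, pairwise deletion is re-applied within each
replicate, and the standard deviation of the replicate distances is
returned. Resampling the full length rather than the pairwise-deleted
subset mirrors how site-bootstrap variance is conventionally documented
for distance software; replicates that end up with no comparable site
(possible for gappy pairs) are excluded. The implementation draws
per-column multinomial counts, which is distribution-identical to
resampling columns and allows a vectorised replicate loop; with the
default 1000 replicates a pair costs well under a millisecond. For the
canonical check — a 4-column pair with one mismatch, where a replicate
distance is Binomial(4, 1/4)/4 — the estimate converges to
sqrt(0.25 × 0.75 / 4) ≈ 0.2165, and the test suite verifies this at
10^5 replicates against the exact central moments.

## Barcoding-gap summary

`withinSpeciesRanges()` and `betweenSpeciesRanges()` collapse the
distance matrix by species label. Species with a single member are
excluded from the within analysis (a range needs a pair) and listed as
such. `estimateCutoff()` then takes

* **cutoff** = the largest within-species maximum over species *not*
  in `excludeSpecies`;
* **gapOk** = every between-species minimum strictly exceeds the
  cutoff;
* **exceptions** = species pairs whose between minimum falls strictly
  below the cutoff.

The `excludeSpecies` argument exists because real genera contain a few
species with unusually high internal variation (long cultivation
histories, under-sampled species), and the practical cut-off is quoted
*after* setting those aside. Which species to set aside is a judgement
call backed by phylogenetic support, so the package takes an explicit
list (default: empty) rather than automating outlier detection. A
between minimum exactly equal to the cutoff fails `gapOk` but is not an
exception — the boundary itself is not an overlap.

## Reference-based mislabel detection

The curation studies this package supports judge mislabels by clade
membership in phylogenetic trees. Tree inference is out of scope here,
so the package substitutes a transparent distance rule: each query is
assigned to the species of its nearest designated reference sequence
(`buildReferencePanel()` enforces that references exist and carry the
`reliable` flag — in practice, holotype or expert-verified sequences).
The statuses are:

* `not_in_genus` — nearest reference farther than `genusCutoff`
  (default 0.05, the complement of a 95% similarity retrieval
  threshold); this gate is checked first, mirroring how extremely
  deviant records are excluded before any species-level call;
* `ambiguous` — best references of two species within `tieEpsilon`
  (default 0: exact ties only); ties are reported, never broken;
* `mislabeled` / `concordant` — assignment differs from / matches the
  given label.

Because a distance classifier is not a tree, published clade-based
mislabel tallies are a shape for the report (counts split by voucher
specimen vs cultured strain, plus a per-query correction table), not
numbers this package attempts to reproduce. Panel members are
classified like any other query — at distance zero to themselves —
since reference status is metadata, not an exclusion.

## Diagnostic fragments

`columnProfiles()` records, per species and column, the set of bases
observed among the species' members, expanding ambiguity codes
(`W → {A,T}`) and counting gaps separately. A column is **diagnostic**
for a species when its residue set is non-empty and disjoint from the
union of every other profiled species' set. Two consequences of the
set-based rule are intentional:

* a column where every other species is gapped is diagnostic —
  presence vs absence in an indel region is exactly what a probe can
  exploit, and published fragment tables contain such indel-spanning
  entries;
* intra-species variation that stays exclusive (e.g. the species shows
  `{A,T}` where all others show `{C}` or `{G}`) still qualifies, so
  reported fragments may contain IUPAC consensus symbols.

`assembleFragments()` merges diagnostic columns left to right:
consecutive diagnostic columns separated by at most `mergeGap`
non-diagnostic columns join one fragment; fragments are trimmed so both
ends are diagnostic and must contain at least `minDiag = 2` diagnostic
columns (a single diagnostic nucleotide is not enough for an assay).
The published tables this mirrors show fragments with interleaved
non-diagnostic columns but never state the merge distance; the default
`mergeGap = 5` is the smallest round value consistent with the geometry
of those tables (for instance a 9-column span containing 4 diagnostic
nucleotides) and is an exposed parameter, not a claim. The fragment
sequence is the species consensus over the span with all-gap columns
dropped, so a span may exceed its sequence length. Labels `A`, `B`,
`C`, ... are assigned jointly across species in span order.

The greedy merge is exactly equivalent to choosing the maximal windows
among all `(start, end)` pairs of diagnostic columns with internal gaps
≤ `mergeGap` — the test suite proves this against an exhaustive
window-enumeration oracle on hundreds of random alignments.

## Synthetic data: what it emulates, what it does not

`simulateBarcodeData()` stands in for a curated database download. The
generative model is deliberately minimal: a uniform random genus
ancestor of length `nColumns`; species roots mutated per site with
probability `pInter`; members mutated from their root with `pIntra`;
substitutions draw a uniformly random different base (a Jukes–Cantor-
like move — no transition bias, no rate heterogeneity). Under this
model the expected p-distance between two members of one species is

&nbsp;&nbsp;&nbsp;&nbsp;E[p] = 2·p(1−p) + p²·(2/3),&nbsp; p = `pIntra`,

(each site differs when exactly one lineage mutates, or both mutate and
land on different bases), which the parameter-recovery tests verify to
within Monte-Carlo error. Optional features exercise specific pipeline
behaviours: indel blocks (Poisson count with mean
`indelBlockRate × nSpecies`, lengths 5–15, gapping all members of one
species) exercise pairwise deletion and gap diagnostics; planted
fragments overwrite the target species at chosen columns and force a
different residue everywhere else, guaranteeing diagnosticity; and
`injectMislabels()` swaps `round(fraction × n)` labels to uniformly
chosen other species. Designated reference ids (the first member of
each species, flagged reliable) are exempt from swapping, so the
reference panel itself stays clean — mislabeled references are a real
phenomenon but a different experiment. Seeds are mandatory everywhere;
nothing in the generator has a hidden default stream.

What the generator does *not* emulate: realistic ITS length and indel
distributions, transition/transversion bias, rate variation across
sites and lineages, coalescent structure within species, or alignment
error. Passing the synthetic recovery tests therefore shows the
pipeline is correct *given* a well-formed alignment with cluster
structure; it does not show that real ITS data meet those assumptions,
and the classifier in particular inherits whatever biases the input
alignment carries.

## Study conditions used by the checks

The reference conditions for the package's own verification runs are 3
species × 5 members × 600 columns at `pIntra = 0.005`,
`pInter = 0.03`, over 20 independent seeds — sizes at which a full
pipeline pass takes seconds while within-species pair counts (30 per
run) give stable means. The same conditions drive
`scripts/acceptance.R`, which recomputes mean within/between distances,
the cut-off, the gap verdict rate, mislabel and planted-fragment
recovery rates, and the canonical bootstrap SE, writing them as JSON.

## Numerical and interface choices

* Coordinates are 1-based inclusive alignment columns at every
  interface, matching how fragment positions are quoted in the
  literature; a fragment `start`/`end` spans `end − start + 1` columns.
* `U` and lowercase input are normalised on read; anything outside the
  IUPAC-plus-gap alphabet is rejected with the offending id and column.
* Strict label/alignment id matching is the default; a loose mode drops
  unmatched label rows with a warning, because curation pipelines meet
  messy metadata.
* Ties in range maxima/minima are resolved by value (ranges are values,
  not pairs); the species attaining the cutoff is logged for
  diagnostics.
* `runPipeline()` aborts on the first failing stage, names it, retains
  partial outputs next to a `FAILED` marker, and writes a manifest
  (package version, config echo, seed, input MD5 checksums) sufficient
  to re-run the analysis exactly; reruns with identical config and seed
  are byte-identical apart from the manifest timestamp.

## Limitations

The distance classifier is a stand-in for tree-based clade reading and
will disagree with it near the gap boundary; species whose within
variation exceeds the between minimum of a neighbouring pair (real
genera have them) produce exceptions that no threshold fixes. The
fragment finder guarantees column-set exclusivity within the analysed
species set only — fragments are diagnostic against the species you
profiled, not against a database. And all percentage reporting rounds
to two decimals at the boundary between "range" and "cut-off", so
downstream consumers should use the JSON proportions, not the printed
percentages, for arithmetic.
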