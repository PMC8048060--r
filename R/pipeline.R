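#' Run the full curation pipeline
#'
#' Orchestrates the analysis end to end: read and validate the alignment
#' and label table, compute the p-distance matrix, summarise within- and
#' between-species ranges and the barcoding-gap cut-off, classify every
#' sequence against the designated reference panel, assemble diagnostic
#' fragments, and write all outputs plus a run manifest to `outDir`.
#'
#' Output files: `distances_square.tsv`, `distances_long.tsv`,
#' `species_summary.tsv`, `summary.json`, `classification.tsv`,
#' `mislabel_report.json`, `fragments.tsv`, `manifest.json`. On a stage
#' failure the error is re-signalled with the stage name, partial outputs
#' are retained and a `FAILED` marker file records the stage and message.
#'
#' @param alignmentFile aligned FASTA path.
#' @param labelsFile species-label TSV path.
#' @param referencesFile reference-designation TSV path (`species`, `id`).
#' @param outDir output directory (created if needed).
#' @param excludeSpecies species excluded from the cut-off maximum.
#' @param genusCutoff genus-membership gate (proportion, default 0.05).
#' @param tieEpsilon classifier tie tolerance (default 0).
#' @param mergeGap fragment merge distance (default 5).
#' @param minDiag minimum diagnostic columns per fragment (default 2).
#' @param diagSpecies species set for fragment discovery (default: all).
#' @param bootstrapReplicates bootstrap replicates for distance SEs
#'   (0 = skip).
#' @param seed integer seed used for the bootstrap.
#' @param strict strict id matching between labels and alignment.
#' @param quiet suppress stage log messages.
#' @return invisibly, a list with all in-memory results (`alignment`,
#'   `labels`, `distances`, `summary`, `classification`, `report`,
#'   `fragments`, `manifest`).
#' @export
runPipeline <- function(alignmentFile, labelsFile, referencesFile, outDir,
    excludeSpecies = character(), genusCutoff = 0.05, tieEpsilon = 0,
    mergeGap = 5L, minDiag = 2L, diagSpecies = NULL,
    bootstrapReplicates = 0L, seed = 1L, strict = TRUE, quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(outDir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    .msg(quiet, sprintf("[%s] started", name))
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
        failed)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE)
    })
    .msg(quiet, sprintf("[%s] done (%.2fs)", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  io <- stage("io", {
    alignment <- readAlignedFasta(alignmentFile)
    labels <- readSpeciesLabels(labelsFile, alignment, strict = strict)
    references <- readReferenceDesignations(referencesFile)
    list(alignment = alignment, labels = labels, references = references)
  })

  pdm <- stage("dist", {
    x <- pDistanceMatrix(io$alignment,
      bootstrapReplicates = bootstrapReplicates, seed = seed)
    writeDistanceMatrix(x,
      squarePath = file.path(outDir, "distances_square.tsv"),
      longPath = file.path(outDir, "distances_long.tsv"))
    x
  })

  summary <- stage("summary", {
    s <- speciesDistanceSummary(pdm, io$labels,
      excludeSpecies = excludeSpecies, quiet = quiet)
    writeSpeciesSummary(s,
      tsvPath = file.path(outDir, "species_summary.tsv"),
      jsonPath = file.path(outDir, "summary.json"))
    s
  })

  cls <- stage("classify", {
    panel <- buildReferencePanel(io$alignment, io$labels, io$references)
    results <- classifySequences(io$alignment, io$labels, panel,
      genusCutoff = genusCutoff, tieEpsilon = tieEpsilon)
    report <- mislabelReport(results, io$labels)
    writeClassification(results, report,
      tsvPath = file.path(outDir, "classification.tsv"),
      jsonPath = file.path(outDir, "mislabel_report.json"))
    list(results = results, report = report)
  })

  fragments <- stage("fragments", {
    f <- diagnosticFragments(io$alignment, io$labels,
      species = diagSpecies, minDiag = minDiag, mergeGap = mergeGap)
    writeFragmentsTable(f[, c("species", "sequence", "start", "end",
      "nDiagnostic")], file.path(outDir, "fragments.tsv"))
    f
  })

  manifest <- stage("manifest", {
    m <- list(
      package = "barcodeGap",
      version = as.character(packageVersion("barcodeGap")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      config = list(
        alignmentFile = alignmentFile, labelsFile = labelsFile,
        referencesFile = referencesFile, outDir = outDir,
        excludeSpecies = excludeSpecies, genusCutoff = genusCutoff,
        tieEpsilon = tieEpsilon, mergeGap = mergeGap, minDiag = minDiag,
        diagSpecies = diagSpecies,
        bootstrapReplicates = bootstrapReplicates, strict = strict),
      input_checksums = as.list(tools::md5sum(
        c(alignmentFile, labelsFile, referencesFile)))
    )
    jsonlite::write_json(m, file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    m
  })

  invisible(list(alignment = io$alignment, labels = io$labels,
    distances = pdm, summary = summary, classification = cls$results,
    report = cls$report, fragments = fragments, manifest = manifest))
}

#' Write a simulated dataset to disk
#'
#' Writes a [simulateBarcodeData()] result as aligned FASTA, label TSV,
#' reference-designation TSV and a truth JSON, ready for [runPipeline()].
#'
#' @param sim result of [simulateBarcodeData()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSimulatedDataset <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    alignment = file.path(outDir, "alignment.fasta"),
    labels = file.path(outDir, "labels.tsv"),
    references = file.path(outDir, "references.tsv"),
    truth = file.path(outDir, "truth.json"))
  writeAlignedFasta(sim$alignment, paths[["alignment"]])
  writeSpeciesLabels(sim$labels, paths[["labels"]])
  write.table(sim$references, paths[["references"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    trueSpecies = as.list(sim$truth$trueSpecies),
    swappedIds = sim$truth$swappedIds,
    plantedFragments = sim$truth$plantedFragments
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
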