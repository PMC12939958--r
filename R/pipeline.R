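#' Run the full matched-lesion analysis pipeline
#'
#' Executes every stage in order on a cohort's tables: germline
#' subtraction and quality filtering, CN-LOH cutoff derivation from the
#' normal reference samples, copy-number event calling and haplotype
#' assignment, per-sample 96-context signature refitting, per-case
#' parsimony trees with topology classification and the shared-variant
#' VAF comparison, driver-gene scoring with threshold sensitivity, and
#' the gated group-burden statistics. Writes per-stage TSVs, Newick
#' trees, a JSON summary and a run log (echoing every threshold
#' actually applied, including the derived CN-LOH cutoff). The run is
#' fully deterministic given its inputs.
#'
#' @param variantTable cohort variant data.frame or TSV path.
#' @param segmentTable cohort segment data.frame or TSV path.
#' @param genes gene table (gene, chrom, start, end, role) or TSV path.
#' @param outDir output directory.
#' @param minMeanBaseQuality,minDepth,minVaf quality-filter thresholds.
#' @param gainCutoff,lossCutoff copy-ratio cutoffs (defaults 1.1, 0.9).
#' @param scoreThreshold candidate-gene threshold (default 2).
#' @param targetSizeMb callable territory for mutation rates (default
#'   the simulated genome size in Mb; supply the exome size for real
#'   data).
#' @param reference 96 x K signature matrix (default the packaged
#'   synthetic mini-reference).
#' @param seed echoed into the summary for provenance (the pipeline
#'   itself draws no random numbers).
#' @return invisibly, a list with all stage results (`somatic`,
#'   `cutoff`, `events`, `exposuresBySample`, `trees`, `topologies`,
#'   `sharedVaf`, `scoring`, `burdenStats`, `summary`).
#' @export
runPipeline <- function(variantTable, segmentTable, genes, outDir,
                        minMeanBaseQuality = 20, minDepth = 10,
                        minVaf = 0.05, gainCutoff = 1.1, lossCutoff = 0.9,
                        scoreThreshold = 2L, targetSizeMb = 220,
                        reference = syntheticSignatureMatrix(),
                        seed = NULL) {
  if (is.character(variantTable)) variantTable <- readVariantTable(variantTable)
  if (is.character(segmentTable)) segmentTable <- readSegmentTable(segmentTable)
  if (is.character(genes)) {
    genes <- .readTsv(genes)
    .checkColumns(genes, c("gene", "chrom", "start", "end", "role"),
                  "gene table")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  say <- function(...) logLines <<- c(logLines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  roleOfSample <- stats::setNames(variantTable$role, variantTable$sample_id)
  roleOfSample <- roleOfSample[!duplicated(names(roleOfSample))]
  say("thresholds: minMeanBaseQuality=", minMeanBaseQuality,
      " minDepth=", minDepth, " minVaf=", minVaf,
      " gainCutoff=", gainCutoff, " lossCutoff=", lossCutoff,
      " scoreThreshold=", scoreThreshold)
  if (!is.null(seed)) say("seed: ", seed)

  ## filter ------------------------------------------------------------
  somatic <- stage("filter", somaticVariants(
    variantTable, minMeanBaseQuality = minMeanBaseQuality,
    minDepth = minDepth, minVaf = minVaf))
  writeVariantTable(somatic, file.path(outDir, "somatic.tsv"))
  say("filter: ", nrow(somatic), " somatic variant rows retained")

  ## cna ---------------------------------------------------------------
  nmSamples <- names(roleOfSample)[roleOfSample == "Nm"]
  normalMafs <- lapply(nmSamples, function(s)
    segmentTable$minor_allele_fraction[segmentTable$sample_id == s])
  names(normalMafs) <- nmSamples
  cutoff <- stage("cna", deriveCnlohCutoff(normalMafs))
  say(sprintf("cna: derived CN-LOH minor-allele-fraction cutoff %.5f from %d normals",
              cutoffValue(cutoff), cutoff@nNormals))
  lesionSegs <- segmentTable[segmentTable$sample_id %in%
                               names(roleOfSample)[roleOfSample != "Nm"], ,
                             drop = FALSE]
  events <- stage("cna", callCnaEvents(lesionSegs, cutoff,
                                       gainCutoff = gainCutoff,
                                       lossCutoff = lossCutoff))
  events <- stage("cna", assignHaplotypes(events, variantTable))
  writeEventTable(events, file.path(outDir, "events.tsv"))
  say("cna: ", nrow(events), " events called")

  ## signatures --------------------------------------------------------
  expoRows <- list()
  exposuresBySample <- list()
  for (s in unique(somatic$sample_id)) {
    sv <- somatic[somatic$sample_id == s, , drop = FALSE]
    snv <- sv[nchar(sv$ref) == 1L & nchar(sv$alt) == 1L &
                !is.na(sv$context), , drop = FALSE]
    if (!nrow(snv)) next
    fit <- stage("signatures",
                 fitExposures(buildSpectrum(snv), reference))
    exposuresBySample[[s]] <- fit
    expoRows[[s]] <- data.frame(sample_id = s, role = roleOfSample[[s]],
                                t(signatureProportions(fit)),
                                stringsAsFactors = FALSE)
  }
  if (length(expoRows))
    .writeTsv(do.call(rbind, expoRows), file.path(outDir, "exposures.tsv"))

  ## phylogeny ---------------------------------------------------------
  trees <- list(); topologies <- list(); sharedVaf <- list()
  dir.create(file.path(outDir, "trees"), showWarnings = FALSE)
  for (cs in sort(unique(somatic$case_id))) {
    cv <- somatic[somatic$case_id == cs, , drop = FALSE]
    if (length(unique(cv$role)) < 2L) next
    bcm <- stage("phylogeny", buildCharacterMatrix(cv))
    tr <- stage("phylogeny", parsimonyTree(bcm))
    trees[[cs]] <- tr
    topologies[[cs]] <- classifyTopology(tr)
    if (tr@nCharacters > 0L && inherits(tr@tree, "phylo"))
      writeNewick(tr, file.path(outDir, "trees", paste0(cs, ".nwk")))
    sharedVaf[[cs]] <- tryCatch({
      sc <- sharedVafComparison(cv, "L", "G")
      list(nShared = sc$nShared, meanL = sc$meanA, meanG = sc$meanB,
           meanDifference = sc$meanDifference, p = pValue(sc$test))
    }, error = function(e) NULL)
  }

  ## scoring -----------------------------------------------------------
  scoring <- stage("scoring", scoreCohort(
    somatic, events, genes, threshold = scoreThreshold))
  .writeTsv(scoring$scores, file.path(outDir, "scores.tsv"))
  say("scoring: ", length(scoring$candidates), " candidate genes at >=",
      scoreThreshold, " points")

  ## burden statistics -------------------------------------------------
  burden <- stats::aggregate(pos ~ sample_id + role, data = somatic,
                             FUN = length)
  names(burden)[names(burden) == "pos"] <- "n_somatic"
  burden$rate_per_mb <- burden$n_somatic / targetSizeMb
  groups <- split(burden$n_somatic, burden$role)
  groups <- groups[names(groups) %in% c("N", "L", "G")]
  burdenStats <- if (length(groups) >= 2L &&
                     all(vapply(groups, length, integer(1)) >= 2L))
    stage("stats", correctedPairwise(groups)) else NULL

  ## summary -----------------------------------------------------------
  summary <- list(
    config = list(minMeanBaseQuality = minMeanBaseQuality,
                  minDepth = minDepth, minVaf = minVaf,
                  gainCutoff = gainCutoff, lossCutoff = lossCutoff,
                  scoreThreshold = scoreThreshold,
                  targetSizeMb = targetSizeMb,
                  seed = if (is.null(seed)) NA else seed),
    cnlohCutoff = round(cutoffValue(cutoff), 6),
    burden = burden,
    sbs1ProportionBySample = lapply(exposuresBySample, function(f)
      round(unname(signatureProportions(f)["SBS1like"]), 6)),
    topologyByCase = topologies,
    sharedVafByCase = sharedVaf,
    candidates = scoring$candidates,
    candidatesByThreshold = scoring$candidatesByThreshold,
    nEvents = nrow(events),
    burdenOmnibusP = if (is.null(burdenStats)) NA else
      round(pValue(burdenStats$omnibus), 8))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       na = "null")
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(list(somatic = somatic, cutoff = cutoff, events = events,
                 exposuresBySample = exposuresBySample, trees = trees,
                 topologies = topologies, sharedVaf = sharedVaf,
                 scoring = scoring, burdenStats = burdenStats,
                 summary = summary))
}
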