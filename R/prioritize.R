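.emptyResults <- function() {
  data.frame(fusionPair = character(0), oncProb = numeric(0),
             gene5Id = character(0), gene5Name = character(0),
             gene5Description = character(0), gene3Id = character(0),
             gene3Name = character(0), gene3Description = character(0),
             mainProteinLength = integer(0), truncated = logical(0),
             fivePrimeComplete = logical(0), threePrimeComplete = logical(0),
             nCandidates = integer(0), mainProtein = character(0),
             sourceRow = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

## pick the main protein: max score, ties by greater length, then (tx5, tx3)
.mainProteinIndex <- function(proteins, scores) {
  ord <- order(-scores, -nchar(proteins$sequence),
               proteins$tx5Id, proteins$tx3Id)
  ord[1]
}

#' Prioritize a set of fusions
#'
#' For every input fusion and every (5' gene, 3' gene) pair overlapping its
#' breakpoints, enumerates all candidate fused proteins, scores each with the
#' model, aggregates per-fusion scores by maximum into the oncogenic
#' probability, and reports the main protein (the candidate achieving the
#' maximum). Fusions for which no protein can be built get `NA` probability
#' and a reason code. Results are ranked non-increasing by probability
#' (stable with respect to input order on ties), `NA` rows last.
#'
#' @param fusions data.frame from [parseFusions()] or [parseCallerFusions()].
#' @param index an [AnnotationIndex-class].
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @param model a [PredictionModel-class].
#' @return ranked data.frame with one row per (fusion, gene pair); columns as
#'   the report schema plus `sourceRow` and `reason`.
#' @export
prioritizeFusions <- function(fusions, index, genome, model) {
  rows <- list()
  for (i in seq_len(nrow(fusions))) {
    fus <- as.list(fusions[i, c("chrom5", "pos5", "chrom3", "pos3",
                                "sourceRow")])
    sets <- enumerateCandidates(fus, index, genome)
    for (cs in sets) {
      g5 <- cs@gene5; g3 <- cs@gene3
      if (nrow(cs@proteins) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          fusionPair = if (is.null(g5)) "NA_NA"
                       else paste0(g5@name, "_", g3@name),
          oncProb = NA_real_,
          gene5Id = if (is.null(g5)) "NA" else g5@geneId,
          gene5Name = if (is.null(g5)) "NA" else g5@name,
          gene5Description = if (is.null(g5)) "NA" else g5@description,
          gene3Id = if (is.null(g3)) "NA" else g3@geneId,
          gene3Name = if (is.null(g3)) "NA" else g3@name,
          gene3Description = if (is.null(g3)) "NA" else g3@description,
          mainProteinLength = 0L, truncated = NA,
          fivePrimeComplete = NA, threePrimeComplete = NA,
          nCandidates = 0L, mainProtein = "",
          sourceRow = fus$sourceRow, reason = cs@reason,
          stringsAsFactors = FALSE)
        next
      }
      scores <- scoreCandidates(model, cs)
      main <- .mainProteinIndex(cs@proteins, scores)
      mp <- cs@proteins[main, ]
      rows[[length(rows) + 1L]] <- data.frame(
        fusionPair = paste0(g5@name, "_", g3@name),
        oncProb = aggregateScores(scores),
        gene5Id = g5@geneId, gene5Name = g5@name,
        gene5Description = g5@description,
        gene3Id = g3@geneId, gene3Name = g3@name,
        gene3Description = g3@description,
        mainProteinLength = nchar(mp$sequence),
        truncated = mp$truncated,
        fivePrimeComplete = mp$fivePrimeComplete,
        threePrimeComplete = mp$threePrimeComplete,
        nCandidates = nrow(cs@proteins),
        mainProtein = mp$sequence,
        sourceRow = fus$sourceRow, reason = "",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else .emptyResults()
  rankResults(res)
}

#' Rank fusion results by oncogenic probability
#'
#' Stable sort: non-increasing probability, ties broken by input order
#' (`sourceRow`); rows with `NA` probability sort after all scored rows.
#'
#' @param results data.frame of fusion results.
#' @return the ranked data.frame.
#' @export
rankResults <- function(results) {
  if (nrow(results) == 0) return(results)
  ord <- order(is.na(results$oncProb), -ifelse(is.na(results$oncProb), 0,
                                               results$oncProb),
               results$sourceRow)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter ranked results at a probability threshold
#'
#' Keeps scored rows with probability greater than or equal to `thr`
#' (boundary values are retained); `NA`-probability rows are dropped from the
#' filtered view but remain available in the full report.
#'
#' @param results ranked data.frame of fusion results.
#' @param thr threshold in [0, 1] (default 0.8).
#' @return the filtered, still-ranked data.frame.
#' @export
rankAndFilter <- function(results, thr = 0.8) {
  if (!is.numeric(thr) || length(thr) != 1 || is.na(thr) ||
      thr < 0 || thr > 1)
    stop("thr must be a number in [0, 1]")
  ranked <- rankResults(results)
  ranked[!is.na(ranked$oncProb) & ranked$oncProb >= thr, , drop = FALSE]
}

#' Run inference end-to-end
#'
#' Parses the fusion input, loads genome, annotation and model, prioritizes
#' every fusion and writes the full ranked report. The threshold controls
#' which rows are counted as relevant in the returned summary; the written
#' report always contains all rows.
#'
#' @param input path to the fusion input file.
#' @param inputFormat `"generic"` or a registered caller format name.
#' @param genomePath path to the genome FASTA.
#' @param gtfPath path to the annotation GTF.
#' @param modelPath path to a model archive from [saveModel()].
#' @param threshold relevance threshold in [0, 1].
#' @param output path for the ranked report.
#' @return invisibly, a list with `results` (full ranked data.frame),
#'   `relevant` (filtered view) and `output`.
#' @export
runInference <- function(input, inputFormat = "generic", genomePath, gtfPath,
                         modelPath, threshold = 0.8, output) {
  genome <- loadGenome(genomePath)
  index <- loadAnnotation(gtfPath, genome)
  model <- loadModel(modelPath)
  fusions <- if (identical(inputFormat, "generic")) parseFusions(input)
             else parseCallerFusions(input, inputFormat)
  results <- prioritizeFusions(fusions, index, genome, model)
  writeFusionReport(results, output)
  relevant <- rankAndFilter(results, threshold)
  message(sprintf("%d fusion row(s) reported, %d at probability >= %.2f",
                  nrow(results), nrow(relevant), threshold))
  invisible(list(results = results, relevant = relevant, output = output))
}

#' Run retraining end-to-end
#'
#' Parses the labeled N x 5 fusion file, builds and balances the labeled
#' protein dataset, trains a fresh model (optionally warm-started) and writes
#' the model archive plus a JSON training report.
#'
#' @param input path to the labeled fusion file (5 columns).
#' @param genomePath path to the genome FASTA.
#' @param gtfPath path to the annotation GTF.
#' @param configPath optional YAML file overriding [modelConfig()] /
#'   [encoderConfig()] values (keys `model:` and `encoder:`).
#' @param seed integer seed (overrides the config seed).
#' @param output path for the model archive.
#' @param reportPath optional path for the JSON training report.
#' @param warmStart optional model archive to initialize weights from.
#' @return invisibly, a list with `model`, `report` and `output`.
#' @export
runRetrain <- function(input, genomePath, gtfPath, configPath = NULL,
                       seed = 1L, output, reportPath = NULL,
                       warmStart = NULL) {
  genome <- loadGenome(genomePath)
  index <- loadAnnotation(gtfPath, genome)
  labeled <- parseFusions(input, labeled = TRUE)

  mArgs <- list(); eArgs <- list()
  if (!is.null(configPath)) {
    cfgFile <- yaml::read_yaml(configPath)
    if (!is.null(cfgFile$model)) mArgs <- cfgFile$model
    if (!is.null(cfgFile$encoder)) eArgs <- cfgFile$encoder
  }
  mArgs$seed <- as.integer(seed)
  cfg <- do.call(modelConfig, mArgs)
  enc <- do.call(encoderConfig, eArgs)

  ds <- buildTrainingSet(labeled, index, genome)
  ds <- balanceDataset(ds, seed = cfg$seed)
  fit <- trainModel(ds, cfg, enc, warmStart = warmStart)
  saveModel(fit$model, output)
  if (!is.null(reportPath))
    jsonlite::write_json(fit$report, reportPath, auto_unbox = TRUE,
                         digits = NA)
  message(sprintf(
    "trained on %d sequences (%d/%d after balancing), %d epoch(s), val AUROC %.3f; archive: %s",
    length(ds@sequences), fit$report$classCounts["n0"],
    fit$report$classCounts["n1"], fit$report$epochsRun,
    fit$report$valAUROC, output))
  invisible(list(model = fit$model, report = fit$report, output = output))
}
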