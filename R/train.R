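#' Build a labeled training set from labeled fusions
#'
#' Enumerates every candidate protein of every labeled fusion; each protein
#' inherits its fusion's 0/1 label. Duplicate sequences are collapsed to one
#' example; sequences observed under both labels are dropped entirely (the
#' conflict count is recorded, not arbitrated).
#'
#' @param labeled data.frame from `parseFusions(..., labeled = TRUE)` (columns
#'   `chrom5`, `pos5`, `chrom3`, `pos3`, `label`, `sourceRow`).
#' @param index an [AnnotationIndex-class].
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @return a [TrainingDataset-class].
#' @export
buildTrainingSet <- function(labeled, index, genome) {
  stopifnot(all(labeled$label %in% c(0L, 1L)))
  seqs <- character(0); labs <- integer(0); prov <- character(0)
  for (i in seq_len(nrow(labeled))) {
    fus <- as.list(labeled[i, c("chrom5", "pos5", "chrom3", "pos3",
                                "sourceRow")])
    sets <- enumerateCandidates(fus, index, genome)
    for (cs in sets) {
      if (nrow(cs@proteins) == 0) next
      seqs <- c(seqs, cs@proteins$sequence)
      labs <- c(labs, rep(labeled$label[i], nrow(cs@proteins)))
      prov <- c(prov, rep(paste0("fusion_", labeled$sourceRow[i]),
                          nrow(cs@proteins)))
    }
  }
  if (length(seqs) == 0)
    stop("empty training set: no candidate protein could be built from the labeled fusions")
  byseq <- split(labs, seqs)
  conflicted <- names(byseq)[vapply(byseq, function(x) length(unique(x)) > 1,
                                    logical(1))]
  keep <- !duplicated(seqs) & !(seqs %in% conflicted)
  new("TrainingDataset", sequences = seqs[keep], labels = labs[keep],
      provenance = prov[keep], conflicts = length(conflicted))
}

#' Balance a training dataset by down-sampling the majority class
#'
#' The minority class is conserved exactly; the majority class is randomly
#' down-sampled (seeded) to the minority size, so class counts differ by at
#' most one (here: zero).
#'
#' @param ds a [TrainingDataset-class] containing both classes.
#' @param seed integer seed for the subsample.
#' @return a balanced [TrainingDataset-class].
#' @export
balanceDataset <- function(ds, seed = 1L) {
  stopifnot(is(ds, "TrainingDataset"))
  n1 <- sum(ds@labels == 1L); n0 <- sum(ds@labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("cannot balance a single-class dataset")
  if (n1 == n0) return(ds)
  minor <- if (n1 < n0) 1L else 0L
  nKeep <- min(n1, n0)
  majIdx <- which(ds@labels != minor)
  keepMaj <- .withSeed(seed, sort(sample(majIdx, nKeep)))
  keep <- sort(c(which(ds@labels == minor), keepMaj))
  new("TrainingDataset", sequences = ds@sequences[keep],
      labels = ds@labels[keep], provenance = ds@provenance[keep],
      conflicts = ds@conflicts)
}

## stratified train/validation split, seeded
.stratifiedSplit <- function(labels, valFrac, seed) {
  .withSeed(seed, {
    valIdx <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nVal <- max(1L, round(length(idx) * valFrac))
      valIdx <- c(valIdx, sample(idx, nVal))
    }
    sort(valIdx)
  })
}

## rank-based AUROC via pROC
.auroc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Train a prediction model
#'
#' Fits the classifier with Adam on binary cross-entropy over a seeded
#' stratified train/validation split, early-stopping on validation loss with
#' the configured patience and restoring the best weights. Training is
#' deterministic given `cfg$seed`. Non-convergence is not an error: the
#' report carries the metrics.
#'
#' @param ds a balanced [TrainingDataset-class] with at least 20 examples.
#' @param cfg a [modelConfig()].
#' @param enc an [encoderConfig()].
#' @param warmStart optional path to a model archive whose weights initialize
#'   training (architecture must match); default is fresh weights.
#' @param verbose print per-epoch losses.
#' @return list with `model` (a [PredictionModel-class]) and `report` (list:
#'   `epochsRun`, `finalTrainLoss`, `valLoss`, `valAccuracy`, `valAUROC`,
#'   `classCounts`, `nTrain`, `nVal`, `valScores`, `valLabels`, `seed`,
#'   `config`).
#' @export
trainModel <- function(ds, cfg = modelConfig(), enc = encoderConfig(),
                       warmStart = NULL, verbose = FALSE) {
  stopifnot(is(ds, "TrainingDataset"))
  n <- length(ds@sequences)
  if (n < 20)
    stop("training requires at least 20 examples, got ", n)

  valIdx <- .stratifiedSplit(ds@labels, cfg$validationSplit, cfg$seed)
  trIdx <- setdiff(seq_len(n), valIdx)
  Xtr <- encodeSequences(ds@sequences[trIdx], enc)
  ytr <- as.numeric(ds@labels[trIdx])
  Xval <- encodeSequences(ds@sequences[valIdx], enc)
  yval <- as.numeric(ds@labels[valIdx])

  w <- if (is.null(warmStart)) .nnInitWeights(cfg, enc, cfg$seed)
       else loadModel(warmStart)@weights
  opt <- .adamInit(w)

  bestLoss <- Inf
  bestW <- w
  wait <- 0L
  epochsRun <- 0L
  trainLoss <- NA_real_

  evalLoss <- function(w) {
    m <- new("PredictionModel", encoder = enc, config = cfg, weights = w)
    p <- .scoreEncoded(m, Xval)
    .bceLoss(p, yval)
  }

  .withSeed(cfg$seed + 1L, {
    nTr <- nrow(Xtr)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(nTr)
      starts <- seq.int(1L, nTr, by = cfg$batchSize)
      lossAcc <- 0
      for (s in starts) {
        bIdx <- ord[s:min(s + cfg$batchSize - 1L, nTr)]
        Xb <- Xtr[bIdx, , drop = FALSE]
        yb <- ytr[bIdx]
        fw <- .nnForward(w, cfg, Xb, training = TRUE)
        lossAcc <- lossAcc + .bceLoss(fw$p, yb) * length(bIdx)
        dpre <- (fw$p - yb) / length(bIdx)
        g <- .nnBackward(w, cfg, fw$cache, dpre)
        upd <- .adamStep(w, g, opt, cfg$learningRate,
                         clipNorm = cfg$clipNorm)
        w <- upd$w
        opt <- upd$state
      }
      trainLoss <- lossAcc / nTr
      vLoss <- evalLoss(w)
      epochsRun <- epoch
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f, val loss %.4f",
                        epoch, trainLoss, vLoss))
      if (vLoss < bestLoss - 1e-6) {
        bestLoss <- vLoss
        bestW <- w
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model <- new("PredictionModel", encoder = enc, config = cfg,
               weights = bestW)
  valScores <- .scoreEncoded(model, Xval)
  report <- list(
    epochsRun = epochsRun,
    finalTrainLoss = trainLoss,
    valLoss = .bceLoss(valScores, yval),
    valAccuracy = mean((valScores >= 0.5) == (yval == 1)),
    valAUROC = .auroc(yval, valScores),
    classCounts = c(n0 = sum(ds@labels == 0L), n1 = sum(ds@labels == 1L)),
    nTrain = length(trIdx), nVal = length(valIdx),
    valScores = valScores, valLabels = yval,
    seed = cfg$seed, config = cfg)
  list(model = model, report = report)
}
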