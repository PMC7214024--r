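#' Build an untrained prediction model
#'
#' Instantiates the classifier — embedding, 1-D convolution with ReLU and
#' temporal max-pooling, bidirectional LSTM, temporal max over the recurrent
#' outputs, dropout, and a single sigmoid output unit — with seeded
#' Glorot-uniform initial weights (forget-gate biases start at 1).
#'
#' @param cfg a [modelConfig()].
#' @param enc an [encoderConfig()].
#' @param seed integer seed for weight initialization (defaults to
#'   `cfg$seed`).
#' @return a [PredictionModel-class].
#' @export
buildModel <- function(cfg = modelConfig(), enc = encoderConfig(),
                       seed = cfg$seed) {
  w <- .nnInitWeights(cfg, enc, seed)
  new("PredictionModel", encoder = enc, config = cfg, weights = w)
}

#' Score amino-acid sequences
#'
#' Deterministic inference pass (no dropout). Scores are sigmoid outputs in
#' [0, 1]; batched evaluation matches sequence-at-a-time evaluation.
#'
#' @param model a [PredictionModel-class].
#' @param seqs character vector of amino-acid sequences.
#' @param batchSize evaluation batch size.
#' @return numeric vector of scores in [0, 1], one per sequence.
#' @export
scoreSequences <- function(model, seqs, batchSize = 64L) {
  if (length(seqs) == 0)
    stop("no sequences to score")
  X <- encodeSequences(seqs, model@encoder)
  .scoreEncoded(model, X, batchSize)
}

.scoreEncoded <- function(model, X, batchSize = 64L) {
  n <- nrow(X)
  out <- numeric(n)
  starts <- seq.int(1L, n, by = batchSize)
  for (s in starts) {
    e <- min(s + batchSize - 1L, n)
    out[s:e] <- .nnForward(model@weights, model@config,
                           X[s:e, , drop = FALSE], training = FALSE)$p
  }
  out
}

#' Score the candidate proteins of a fusion candidate set
#'
#' @param model a [PredictionModel-class].
#' @param cset a [FusionCandidateSet-class] with at least one protein.
#' @return numeric vector of scores, one per row of `cset@proteins`.
#' @export
scoreCandidates <- function(model, cset) {
  stopifnot(is(cset, "FusionCandidateSet"))
  if (nrow(cset@proteins) == 0)
    stop("cannot score an empty candidate set (reason: ", cset@reason, ")")
  scoreSequences(model, cset@proteins$sequence)
}

#' Aggregate per-protein scores into the fusion's oncogenic probability
#'
#' The oncogenic probability of a fusion is the maximum of the scores of its
#' candidate proteins, so a single high-scoring protein suffices to flag the
#' fusion.
#'
#' @param scores non-empty numeric vector of scores in [0, 1].
#' @return the maximum score.
#' @export
aggregateScores <- function(scores) {
  if (length(scores) == 0)
    stop("cannot aggregate an empty score list")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop("scores must be in [0, 1]")
  max(scores)
}

## ---- model archive ---------------------------------------------------------

.MODEL_FORMAT <- "fusionDriveR-model"

#' Save a prediction model archive
#'
#' Writes a single self-contained JSON file holding the encoder
#' configuration, the hyperparameters and all weight tensors at full
#' precision, loadable by [loadModel()] for inference or warm-starting.
#'
#' @param model a [PredictionModel-class].
#' @param path output path (conventionally `.json`).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PredictionModel"))
  weights <- lapply(model@weights, function(x) {
    list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.vector(x))
  })
  obj <- list(format = .MODEL_FORMAT, version = 1L,
              encoder = model@encoder, config = model@config,
              weights = weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a prediction model archive
#'
#' @param path path written by [saveModel()].
#' @return a [PredictionModel-class] whose scores reproduce the saved model's.
#' @export
loadModel <- function(path) {
  if (!file.exists(path))
    stop("model archive not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, .MODEL_FORMAT))
    stop("not a model archive: ", path)
  enc <- obj$encoder
  enc$maxLen <- as.integer(enc$maxLen)
  cfg <- do.call(modelConfig, obj$config[names(obj$config) %in%
                                           names(formals(modelConfig))])
  w <- lapply(obj$weights, function(x) {
    if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2])
    else as.numeric(x$data)
  })
  new("PredictionModel", encoder = enc, config = cfg, weights = w)
}
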