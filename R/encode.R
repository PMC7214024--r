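#' Encoder configuration
#'
#' Amino-acid sequences are index-encoded over the ordered alphabet of the 20
#' standard residues plus `X` (unknown), padded with 0 at the tail up to
#' `maxLen` and truncated at the tail beyond it. Index encoding (rather than
#' one-hot) pairs with the model's embedding layer.
#'
#' @param maxLen maximum encoded length in residues (default 1500; longer
#'   sequences are tail-truncated).
#' @return list with `maxLen` and `alphabet`.
#' @export
encoderConfig <- function(maxLen = 1500L) {
  maxLen <- as.integer(maxLen)
  stopifnot(maxLen >= 1)
  list(maxLen = maxLen,
       alphabet = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"))
}

#' Encode amino-acid sequences to fixed-length integer vectors
#'
#' @param seqs character vector of non-empty amino-acid sequences.
#' @param enc an [encoderConfig()].
#' @return integer matrix `length(seqs) x maxLen`; residues are mapped to
#'   `1..21` (alphabet index), unknown residues to the index of `X`, padding
#'   is 0.
#' @export
encodeSequences <- function(seqs, enc) {
  if (length(seqs) == 0)
    stop("no sequences to encode")
  if (any(!nzchar(seqs)))
    stop("cannot encode an empty sequence")
  L <- enc$maxLen
  xIdx <- match("X", enc$alphabet)
  out <- matrix(0L, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (length(ch) > L) ch <- ch[seq_len(L)]
    v <- match(ch, enc$alphabet)
    v[is.na(v)] <- xIdx
    out[i, seq_along(v)] <- v
  }
  out
}

#' Decode one encoded vector back to a sequence
#'
#' Inverse of [encodeSequences()] for sequences no longer than `maxLen`.
#'
#' @param vec integer vector of alphabet indices with 0 padding.
#' @param enc an [encoderConfig()].
#' @return character scalar.
#' @export
decodeSequence <- function(vec, enc) {
  vec <- vec[vec != 0L]
  paste(enc$alphabet[vec], collapse = "")
}

#' Model configuration
#'
#' Hyperparameters of the embedding -> 1-D convolution -> bidirectional LSTM
#' -> sigmoid classifier and of its training loop. All values are positive
#' and overridable.
#'
#' @param embeddingDim embedding dimension per residue.
#' @param convFilters number of convolution filters.
#' @param convKernel convolution kernel width (residues).
#' @param poolSize max-pooling width after the convolution.
#' @param lstmUnits LSTM units per direction.
#' @param dropout dropout rate applied before the dense head during training.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param validationSplit held-out fraction for validation.
#' @param clipNorm global gradient-norm clip.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return a validated list of hyperparameters.
#' @export
modelConfig <- function(embeddingDim = 16L, convFilters = 64L,
                        convKernel = 7L, poolSize = 4L, lstmUnits = 64L,
                        dropout = 0.3, learningRate = 1e-3, batchSize = 32L,
                        epochs = 20L, patience = 5L, validationSplit = 0.2,
                        clipNorm = 5, seed = 1L) {
  cfg <- list(embeddingDim = as.integer(embeddingDim),
              convFilters = as.integer(convFilters),
              convKernel = as.integer(convKernel),
              poolSize = as.integer(poolSize),
              lstmUnits = as.integer(lstmUnits),
              dropout = dropout, learningRate = learningRate,
              batchSize = as.integer(batchSize), epochs = as.integer(epochs),
              patience = as.integer(patience),
              validationSplit = validationSplit, clipNorm = clipNorm,
              seed = as.integer(seed))
  numeric <- c("embeddingDim", "convFilters", "convKernel", "poolSize",
               "lstmUnits", "learningRate", "batchSize", "epochs", "patience",
               "clipNorm")
  for (nm in numeric)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("hyperparameter '", nm, "' must be positive")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must be in [0, 1)")
  if (cfg$validationSplit <= 0 || cfg$validationSplit >= 1)
    stop("validationSplit must be in (0, 1)")
  cfg
}
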