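#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols
NULL

#' Transcript model
#'
#' One transcript isoform: ordered exon and CDS intervals on a single contig,
#' plus start/stop-codon annotation flags. Coordinates are 1-based inclusive
#' genomic positions; exons are stored in genomic order regardless of strand.
#' For coding transcripts the stored CDS includes the stop codon (appended
#' from the `stop_codon` feature when the GTF follows the Ensembl convention
#' of excluding it), so that translation of the spliced CDS ends at the
#' terminal stop.
#'
#' @slot txId transcript identifier.
#' @slot geneId identifier of the parent gene.
#' @slot contig contig (chromosome) name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon intervals, sorted, non-overlapping.
#' @slot cds [IRanges::IRanges] of CDS intervals (empty for non-coding).
#' @slot hasStart `TRUE` if a start codon is annotated or inferred.
#' @slot hasStop `TRUE` if a stop codon is annotated or inferred.
#' @slot biotype transcript biotype string (e.g. `"protein_coding"`).
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    txId = "character",
    geneId = "character",
    contig = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges",
    hasStart = "logical",
    hasStop = "logical",
    biotype = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character(0)
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) > 1) {
    if (is.unsorted(start(ex)))
      msgs <- c(msgs, "exons must be sorted in genomic order")
    if (any(start(ex)[-1] <= end(ex)[-length(ex)]))
      msgs <- c(msgs, "exons must be non-overlapping")
  }
  cds <- object@cds
  if (length(cds) > 0) {
    contained <- vapply(seq_along(cds), function(i) {
      any(start(cds)[i] >= start(ex) & end(cds)[i] <= end(ex))
    }, logical(1))
    if (!all(contained))
      msgs <- c(msgs, "every CDS interval must lie within an exon")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene model
#'
#' A gene with its span and member transcripts.
#'
#' @slot geneId Ensembl-style gene identifier.
#' @slot name gene symbol.
#' @slot description free-text description.
#' @slot contig contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot spanStart,spanEnd 1-based inclusive genomic span covering all
#'   member transcripts.
#' @slot transcripts list of [TranscriptModel-class] objects.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    name = "character",
    description = "character",
    contig = "character",
    strand = "character",
    spanStart = "integer",
    spanEnd = "integer",
    transcripts = "list"
  )
)

setValidity("GeneModel", function(object) {
  msgs <- character(0)
  for (tx in object@transcripts) {
    if (!is(tx, "TranscriptModel")) {
      msgs <- c(msgs, "transcripts must be TranscriptModel objects")
      break
    }
    if (length(tx@exons) &&
        (min(start(tx@exons)) < object@spanStart ||
         max(end(tx@exons)) > object@spanEnd))
      msgs <- c(msgs, sprintf("span does not cover transcript %s", tx@txId))
  }
  if (length(msgs)) msgs else TRUE
})

#' Annotation index
#'
#' Container for the parsed gene annotation: all genes (keyed by gene id) plus
#' a [GenomicRanges::GRanges] of gene spans supporting strand-agnostic
#' position queries via [genesAt()].
#'
#' @slot genes named list of [GeneModel-class], sorted by gene id.
#' @slot geneRanges `GRanges` of gene spans with a `gene_id` metadata column.
#' @slot contigs character vector of contig names known to the genome the
#'   annotation was loaded against.
#' @exportClass AnnotationIndex
setClass("AnnotationIndex",
  representation(
    genes = "list",
    geneRanges = "GRanges",
    contigs = "character"
  )
)

setValidity("AnnotationIndex", function(object) {
  ids <- names(object@genes)
  if (is.null(ids) && length(object@genes) > 0)
    return("genes must be a named list keyed by gene id")
  if (anyDuplicated(ids))
    return("gene ids must be unique")
  if (length(ids) > 1 && is.unsorted(ids))
    return("genes must be sorted by gene id")
  TRUE
})

#' Candidate proteins for one (5' gene, 3' gene) pair of a fusion
#'
#' All distinct chimeric proteins obtained by joining each coding transcript
#' of the upstream gene to each coding transcript of the downstream gene at
#' the fusion breakpoints. Transcript pairs for which no protein can be built
#' (for example a 5' breakpoint upstream of the start codon) are recorded in
#' `skipped` with a reason code rather than silently dropped.
#'
#' @slot fusion list with `chrom5`, `pos5`, `chrom3`, `pos3`, `sourceRow`.
#' @slot gene5,gene3 [GeneModel-class] references (may be `NULL` when no gene
#'   overlaps a breakpoint).
#' @slot proteins data.frame with one row per distinct candidate protein:
#'   `sequence`, `tx5Id`, `tx3Id`, `junctionAA`, `inFrame`, `truncated`,
#'   `fivePrimeComplete`, `threePrimeComplete`.
#' @slot skipped data.frame of failed transcript pairs: `tx5Id`, `tx3Id`,
#'   `reason`.
#' @slot reason non-empty reason code when `proteins` is empty.
#' @exportClass FusionCandidateSet
setClass("FusionCandidateSet",
  representation(
    fusion = "list",
    gene5 = "ANY",
    gene3 = "ANY",
    proteins = "data.frame",
    skipped = "data.frame",
    reason = "character"
  )
)

setValidity("FusionCandidateSet", function(object) {
  p <- object@proteins
  if (nrow(p) > 0 && anyDuplicated(p$sequence))
    return("candidate proteins must be unique by sequence")
  if (nrow(p) == 0 && !nzchar(object@reason))
    return("an empty candidate set must carry a reason code")
  TRUE
})

#' Prediction model
#'
#' The sequence classifier: an encoder configuration (alphabet, maximum
#' length, padding policy), the network hyperparameters, and the trained
#' weight tensors of the embedding -> 1-D convolution -> bidirectional LSTM
#' -> sigmoid architecture. Scores are probabilities in [0, 1].
#'
#' @slot encoder list, see [encoderConfig()].
#' @slot config list, see [modelConfig()].
#' @slot weights named list of numeric matrices/vectors.
#' @exportClass PredictionModel
setClass("PredictionModel",
  representation(
    encoder = "list",
    config = "list",
    weights = "list"
  )
)

#' Labeled training dataset
#'
#' Deduplicated labeled amino-acid sequences derived from labeled fusions
#' (each candidate protein inherits its fusion's label) or supplied directly.
#'
#' @slot sequences character vector of amino-acid sequences.
#' @slot labels integer vector of 0/1 oncogenicity labels.
#' @slot provenance character vector identifying the originating fusion.
#' @slot conflicts number of sequences dropped for appearing with both labels.
#' @exportClass TrainingDataset
setClass("TrainingDataset",
  representation(
    sequences = "character",
    labels = "integer",
    provenance = "character",
    conflicts = "integer"
  )
)

setValidity("TrainingDataset", function(object) {
  if (length(object@sequences) != length(object@labels))
    return("sequences and labels must have equal length")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  if (anyDuplicated(object@sequences))
    return("sequences must be deduplicated")
  TRUE
})

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf(
    "TranscriptModel %s (gene %s) %s%s: %d exon(s), CDS %d nt%s\n",
    object@txId, object@geneId, object@contig, object@strand,
    length(object@exons), sum(width(object@cds)),
    if (length(object@cds) == 0) " (non-coding)" else ""
  ))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf(
    "GeneModel %s (%s) %s%s:%d-%d, %d transcript(s)\n",
    object@geneId, object@name, object@contig, object@strand,
    object@spanStart, object@spanEnd, length(object@transcripts)
  ))
})

setMethod("show", "AnnotationIndex", function(object) {
  nTx <- sum(vapply(object@genes, function(g) length(g@transcripts), integer(1)))
  cat(sprintf(
    "AnnotationIndex: %d gene(s), %d transcript(s) on %d contig(s)\n",
    length(object@genes), nTx, length(object@contigs)
  ))
  cat("  contigs:", paste(object@contigs, collapse = ", "), "\n")
})

setMethod("show", "FusionCandidateSet", function(object) {
  f <- object@fusion
  g5 <- if (is.null(object@gene5)) "?" else object@gene5@geneId
  g3 <- if (is.null(object@gene3)) "?" else object@gene3@geneId
  cat(sprintf(
    "FusionCandidateSet %s:%d -> %s:%d [%s -> %s]: %d protein(s), %d skipped%s\n",
    f$chrom5, f$pos5, f$chrom3, f$pos3, g5, g3,
    nrow(object@proteins), nrow(object@skipped),
    if (nzchar(object@reason)) paste0(" (", object@reason, ")") else ""
  ))
})

setMethod("show", "PredictionModel", function(object) {
  nPar <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf(
    "PredictionModel: maxLen %d, embedding %d, %d conv filters (kernel %d), %d LSTM units/direction, %d parameters\n",
    object@encoder$maxLen, object@config$embeddingDim,
    object@config$convFilters, object@config$convKernel,
    object@config$lstmUnits, nPar
  ))
})

setMethod("show", "TrainingDataset", function(object) {
  cat(sprintf(
    "TrainingDataset: %d sequences (%d oncogenic / %d not), %d label conflict(s) dropped\n",
    length(object@sequences), sum(object@labels == 1L),
    sum(object@labels == 0L), object@conflicts
  ))
})
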