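## Transcript-coordinate machinery.
##
## Breakpoint semantics: the 5' coordinate is the LAST genomic base retained
## from the upstream gene; the 3' coordinate is the FIRST genomic base
## retained from the downstream gene, both read in transcript orientation on
## minus-strand genes. Intronic breakpoints retain exons wholly on the kept
## side; the breakpoint never creates novel exonic sequence (fusion
## transcripts are spliced products).

## exon table in transcript order: genomic interval + transcript-coordinate span
.txExonTable <- function(tx) {
  gs <- IRanges::start(tx@exons)
  ge <- IRanges::end(tx@exons)
  if (tx@strand == "-") {
    ord <- rev(seq_along(gs))
    gs <- gs[ord]; ge <- ge[ord]
  }
  w <- ge - gs + 1L
  tEnd <- cumsum(w)
  tStart <- tEnd - w + 1L
  data.frame(gStart = gs, gEnd = ge, tStart = tStart, tEnd = tEnd)
}

## classify a genomic position against a transcript, in transcript orientation
## returns list(region = exonic|intronic|upstream|downstream, t, afterExon)
.g2t <- function(tab, strand, gpos) {
  n <- nrow(tab)
  inExon <- which(gpos >= tab$gStart & gpos <= tab$gEnd)
  if (length(inExon) == 1) {
    i <- inExon
    t <- if (strand == "+") tab$tStart[i] + (gpos - tab$gStart[i])
         else tab$tStart[i] + (tab$gEnd[i] - gpos)
    return(list(region = "exonic", t = as.integer(t), afterExon = i))
  }
  if (strand == "+") {
    if (gpos < tab$gStart[1]) return(list(region = "upstream"))
    if (gpos > tab$gEnd[n]) return(list(region = "downstream"))
    afterExon <- max(which(tab$gEnd < gpos))
  } else {
    if (gpos > tab$gEnd[1]) return(list(region = "upstream"))
    if (gpos < tab$gStart[n]) return(list(region = "downstream"))
    afterExon <- max(which(tab$gStart > gpos))
  }
  list(region = "intronic", afterExon = afterExon)
}

## last retained transcript coordinate on the 5' side (0 = nothing retained)
.boundary5 <- function(tab, strand, gpos) {
  loc <- .g2t(tab, strand, gpos)
  switch(loc$region,
    exonic = loc$t,
    upstream = 0L,
    downstream = tab$tEnd[nrow(tab)],
    intronic = tab$tEnd[loc$afterExon])
}

## first retained transcript coordinate on the 3' side (txLen+1 = nothing)
.boundary3 <- function(tab, strand, gpos) {
  txLen <- tab$tEnd[nrow(tab)]
  loc <- .g2t(tab, strand, gpos)
  switch(loc$region,
    exonic = loc$t,
    upstream = 1L,
    downstream = txLen + 1L,
    intronic = tab$tStart[loc$afterExon + 1L])
}

## transcript-coordinate span of the CDS (first base of start codon, last
## base of the stored CDS, i.e. including the stop codon when annotated)
.cdsTxSpan <- function(tx, tab) {
  cs <- IRanges::start(tx@cds)
  ce <- IRanges::end(tx@cds)
  if (tx@strand == "+") {
    first <- min(cs); last <- max(ce)
  } else {
    first <- max(ce); last <- min(cs)
  }
  tFirst <- .g2t(tab, tx@strand, first)$t
  tLast <- .g2t(tab, tx@strand, last)$t
  list(start = tFirst, end = tLast)
}

#' Build the fused transcript for one transcript pair
#'
#' Joins the upstream transcript's sequence from its annotated start codon
#' through the breakpoint-retained boundary with the downstream transcript's
#' sequence from the breakpoint-retained boundary through its annotated
#' transcript end (both in transcript orientation). Exonic breakpoints may
#' cut mid-codon (the junction codon then mixes bases from both genes);
#' intronic breakpoints retain whole exons on the kept side.
#'
#' @param tx5,tx3 coding [TranscriptModel-class] objects.
#' @param bp5,bp3 genomic breakpoint coordinates on the transcripts' contigs
#'   (5': last retained base; 3': first retained base).
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @return on success, a list with `fused` (nucleotide string starting at the
#'   5' start codon), `junctionOffset` (length of the 5' portion),
#'   `stopOffset` (1-based position in `fused` of the first base of the
#'   downstream transcript's annotated stop codon, `NA` if unannotated),
#'   `inFrame`, `fivePrimeComplete`, `threePrimeComplete`; on failure a list
#'   with a single `reason` element (`"no_cds_retained_5p"`,
#'   `"no_cds_retained_3p"`, `"no_start_codon_5p"`).
#' @export
buildFusedTranscript <- function(tx5, bp5, tx3, bp3, genome) {
  if (length(tx5@cds) == 0 || length(tx3@cds) == 0)
    stop("both transcripts must be coding")
  if (!tx5@hasStart)
    return(list(reason = "no_start_codon_5p"))

  tab5 <- .txExonTable(tx5)
  tab3 <- .txExonTable(tx3)
  span5 <- .cdsTxSpan(tx5, tab5)
  span3 <- .cdsTxSpan(tx3, tab3)
  txLen3 <- tab3$tEnd[nrow(tab3)]

  t5 <- .boundary5(tab5, tx5@strand, bp5)
  # require the full start codon of the upstream gene to be retained
  if (t5 < span5$start + 2L)
    return(list(reason = "no_cds_retained_5p"))

  t3 <- .boundary3(tab3, tx3@strand, bp3)
  stopStart3 <- if (tx3@hasStop) span3$end - 2L else NA_integer_
  # nothing coding gained when the retained portion begins after the first
  # base of the downstream stop codon (or after the CDS when no stop)
  lastUseful <- if (tx3@hasStop) stopStart3 else span3$end
  if (t3 > lastUseful)
    return(list(reason = "no_cds_retained_3p"))

  seq5 <- splicedSequence(tx5, genome, "exons")
  seq3 <- splicedSequence(tx3, genome, "exons")
  part5 <- substring(seq5, span5$start, t5)
  part3 <- substring(seq3, t3, txLen3)
  junctionOffset <- nchar(part5)

  stopOffset <- if (tx3@hasStop) junctionOffset + (stopStart3 - t3 + 1L)
                else NA_integer_

  # frame check: the first retained downstream CDS base must sit at its
  # native codon phase in fused coordinates
  r <- max(t3, span3$start)
  nativePhase <- (r - span3$start) %% 3L
  fusedPos <- junctionOffset + (r - t3 + 1L)
  inFrame <- ((fusedPos - 1L) %% 3L) == nativePhase

  fivePrimeComplete <- tx5@hasStop && t5 >= span5$end
  threePrimeComplete <- tx3@hasStart && t3 <= span3$start

  list(fused = paste0(part5, part3), junctionOffset = junctionOffset,
       stopOffset = stopOffset, inFrame = inFrame,
       fivePrimeComplete = fivePrimeComplete,
       threePrimeComplete = threePrimeComplete)
}

## standard genetic code lookup; codons containing anything outside ACGT
## (typically N) become X
.translateCodons <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return(character(0))
  codons <- substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Translate a fused transcript
#'
#' Codon-by-codon translation with the standard genetic code starting at
#' position 1 (the upstream gene's annotated `ATG`), stopping at the first
#' stop codon. The protein is truncated when that stop is not the downstream
#' transcript's annotated stop codon (or when no stop occurs at all). Codons
#' containing `N` translate to `X`.
#'
#' @param fusedNt fused nucleotide string beginning at the 5' start codon.
#' @param junctionOffset length of the 5'-derived portion.
#' @param stopOffset 1-based position of the first base of the downstream
#'   transcript's annotated stop codon within `fusedNt` (`NA` if none).
#' @return list with `sequence` (amino-acid string), `truncated` (logical)
#'   and `junctionAA` (1-based index of the first residue encoded fully or
#'   partly by the downstream gene; `length + 1` when translation stopped
#'   before reaching it), or a list with a single `reason = "too_short"`.
#' @examples
#' translateFused("ATGGCTTAA", 6L, 7L)  # "MA", not truncated
#' @export
translateFused <- function(fusedNt, junctionOffset, stopOffset) {
  if (nchar(fusedNt) < 3)
    return(list(reason = "too_short"))
  aa <- .translateCodons(fusedNt)
  stopIdx <- which(aa == "*")
  if (length(stopIdx) == 0) {
    protein <- paste(aa, collapse = "")
    truncated <- TRUE
  } else {
    s <- stopIdx[1]
    protein <- paste(aa[seq_len(s - 1L)], collapse = "")
    codonStartNt <- (s - 1L) * 3L + 1L
    truncated <- is.na(stopOffset) || codonStartNt != stopOffset
  }
  len <- nchar(protein)
  if (len == 0)
    return(list(reason = "too_short"))
  jcod <- junctionOffset %/% 3L + 1L
  junctionAA <- if (len >= jcod) jcod else len + 1L
  list(sequence = protein, truncated = truncated, junctionAA = junctionAA)
}

#' Gene-completeness flags for one transcript pair
#'
#' `fivePrimeComplete` is `TRUE` iff the retained upstream portion includes
#' the upstream transcript's annotated stop codon (the whole upstream CDS is
#' in the fusion); `threePrimeComplete` is `TRUE` iff the retained downstream
#' portion includes the downstream transcript's annotated start codon.
#'
#' @inheritParams buildFusedTranscript
#' @return named logical vector with elements `fivePrimeComplete` and
#'   `threePrimeComplete`.
#' @export
completenessFlags <- function(tx5, bp5, tx3, bp3) {
  tab5 <- .txExonTable(tx5)
  tab3 <- .txExonTable(tx3)
  span5 <- .cdsTxSpan(tx5, tab5)
  span3 <- .cdsTxSpan(tx3, tab3)
  t5 <- .boundary5(tab5, tx5@strand, bp5)
  t3 <- .boundary3(tab3, tx3@strand, bp3)
  c(fivePrimeComplete = tx5@hasStop && t5 >= span5$end,
    threePrimeComplete = tx3@hasStart && t3 <= span3$start)
}

.emptyProteins <- function() {
  data.frame(sequence = character(0), tx5Id = character(0),
             tx3Id = character(0), junctionAA = integer(0),
             inFrame = logical(0), truncated = logical(0),
             fivePrimeComplete = logical(0), threePrimeComplete = logical(0),
             stringsAsFactors = FALSE)
}

.emptySkipped <- function() {
  data.frame(tx5Id = character(0), tx3Id = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

.candidateSetForPair <- function(fusion, gene5, gene3, genome) {
  tx5s <- codingTranscripts(gene5)
  tx3s <- codingTranscripts(gene3)
  skipped <- .emptySkipped()
  rows <- list()
  if (length(tx5s) == 0 || length(tx3s) == 0) {
    reason <- if (length(tx5s) == 0) "no_coding_transcripts_5p"
              else "no_coding_transcripts_3p"
    return(new("FusionCandidateSet", fusion = fusion, gene5 = gene5,
               gene3 = gene3, proteins = .emptyProteins(),
               skipped = skipped, reason = reason))
  }
  for (tx5 in tx5s) {
    for (tx3 in tx3s) {
      b <- buildFusedTranscript(tx5, fusion$pos5, tx3, fusion$pos3, genome)
      if (!is.null(b$reason)) {
        skipped <- rbind(skipped, data.frame(
          tx5Id = tx5@txId, tx3Id = tx3@txId, reason = b$reason,
          stringsAsFactors = FALSE))
        next
      }
      tr <- translateFused(b$fused, b$junctionOffset, b$stopOffset)
      if (!is.null(tr$reason)) {
        skipped <- rbind(skipped, data.frame(
          tx5Id = tx5@txId, tx3Id = tx3@txId, reason = tr$reason,
          stringsAsFactors = FALSE))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = tr$sequence, tx5Id = tx5@txId, tx3Id = tx3@txId,
        junctionAA = tr$junctionAA, inFrame = b$inFrame,
        truncated = tr$truncated,
        fivePrimeComplete = b$fivePrimeComplete,
        threePrimeComplete = b$threePrimeComplete,
        stringsAsFactors = FALSE)
    }
  }
  proteins <- if (length(rows)) do.call(rbind, rows) else .emptyProteins()
  if (nrow(proteins) > 0) {
    proteins <- proteins[order(proteins$tx5Id, proteins$tx3Id), , drop = FALSE]
    proteins <- proteins[!duplicated(proteins$sequence), , drop = FALSE]
    rownames(proteins) <- NULL
  }
  reason <- if (nrow(proteins) == 0) {
    if (nrow(skipped) > 0) paste(sort(unique(skipped$reason)), collapse = ",")
    else "no_candidate_protein"
  } else ""
  new("FusionCandidateSet", fusion = fusion, gene5 = gene5, gene3 = gene3,
      proteins = proteins, skipped = skipped, reason = reason)
}

#' Enumerate all candidate fused proteins for a fusion
#'
#' Resolves the genes overlapping each breakpoint and, for every
#' (5' gene, 3' gene) pair, attempts one fused protein per pair of coding
#' transcripts. Within a set, candidates are sorted by `(tx5Id, tx3Id)` and
#' deduplicated by amino-acid sequence; transcript pairs that cannot yield a
#' protein are recorded with a reason code. When no gene overlaps one of the
#' breakpoints a single empty set with reason `"no_gene_at_breakpoint"` is
#' returned.
#'
#' @param fusion a list (or single data.frame row) with `chrom5`, `pos5`,
#'   `chrom3`, `pos3` and optionally `sourceRow`.
#' @param index an [AnnotationIndex-class].
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @return list of [FusionCandidateSet-class], ordered by
#'   `(gene5 id, gene3 id)`.
#' @export
enumerateCandidates <- function(fusion, index, genome) {
  fusion <- as.list(fusion)
  fusion$pos5 <- as.integer(fusion$pos5)
  fusion$pos3 <- as.integer(fusion$pos3)
  if (is.null(fusion$sourceRow)) fusion$sourceRow <- 0L
  for (ct in c(fusion$chrom5, fusion$chrom3))
    if (!ct %in% names(genome))
      stop("unknown contig: ", ct)
  genes5 <- genesAt(index, fusion$chrom5, fusion$pos5)
  genes3 <- genesAt(index, fusion$chrom3, fusion$pos3)
  if (length(genes5) == 0 || length(genes3) == 0) {
    return(list(new("FusionCandidateSet", fusion = fusion,
                    gene5 = NULL, gene3 = NULL,
                    proteins = .emptyProteins(), skipped = .emptySkipped(),
                    reason = "no_gene_at_breakpoint")))
  }
  out <- list()
  for (g5 in genes5)
    for (g3 in genes3)
      out[[length(out) + 1L]] <- .candidateSetForPair(fusion, g5, g3, genome)
  out
}
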