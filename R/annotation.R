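#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   reverseComplement GENETIC_CODE
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Load a genome from FASTA
#'
#' Reads every record of a FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and `U` is mapped to `T`, so downstream code only
#' ever sees the alphabet `{A, C, G, T, N}` (IUPAC ambiguity codes other than
#' `N` are preserved as-is by Biostrings but never produced by the fixture
#' generator).
#'
#' @param fastaPath path to a FASTA file.
#' @return a `DNAStringSet` keyed by contig name (first whitespace-delimited
#'   token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "acgt"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(fastaPath) {
  if (!file.exists(fastaPath))
    stop("genome FASTA not found: ", fastaPath)
  if (file.size(fastaPath) == 0)
    stop("genome FASTA is empty: ", fastaPath)
  # read as raw strings first: uppercase and map U->T (RNA input) before
  # coercing, since the DNA reader would drop U as an invalid letter
  raw <- Biostrings::readBStringSet(fastaPath)
  if (length(raw) == 0)
    stop("genome FASTA contains no records: ", fastaPath)
  nm <- sub("\\s.*$", "", names(raw))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate contig name(s) in FASTA: ", paste(dup, collapse = ", "))
  gen <- Biostrings::DNAStringSet(chartr("U", "T", toupper(as.character(raw))))
  names(gen) <- nm
  gen
}

#' Extract a genomic sub-interval
#'
#' 1-based inclusive lookup returning exactly `end - start + 1` bases.
#' Out-of-range access is an error, never silent clipping.
#'
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @param contig contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return a character scalar.
#' @export
genomeSubseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome))
    stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  if (start < 1 || end > len || start > end)
    stop(sprintf("interval %d-%d out of range for contig %s (length %d)",
                 start, end, contig, len))
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

## quick structural scan so parse failures report a line number, which
## rtracklayer's importer does not
.scanGtfLines <- function(gtfPath) {
  lines <- readLines(gtfPath, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nFields <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nFields < 9)
      stop(sprintf("unparseable GTF line %d: expected 9 tab-separated fields, found %d",
                   i, nFields))
  }
  invisible(TRUE)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Load a gene annotation from GTF
#'
#' Parses an Ensembl-dialect GTF (via [rtracklayer::import()]) into an
#' [AnnotationIndex-class]. Exons and CDS intervals are assembled per
#' transcript and sorted in genomic order. Start/stop flags come from
#' `start_codon` / `stop_codon` features when present, otherwise they are
#' inferred from the CDS termini against the genome sequence. Following the
#' Ensembl convention in which the stop codon is excluded from CDS features,
#' an annotated stop codon is merged into the stored CDS so that spliced CDS
#' extraction ends at the terminal stop.
#'
#' Transcripts whose contig is absent from `genome`, or whose CDS is not
#' contained in their exons, are excluded with a single warning giving counts.
#'
#' @param gtfPath path to a GTF file.
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @return an [AnnotationIndex-class].
#' @export
loadAnnotation <- function(gtfPath, genome) {
  if (!file.exists(gtfPath))
    stop("annotation GTF not found: ", gtfPath)
  .scanGtfLines(gtfPath)
  gr <- rtracklayer::import(gtfPath, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% colnames(md))
    stop("GTF has no gene_id attribute")
  type <- as.character(md$type)
  txId <- if ("transcript_id" %in% colnames(md)) as.character(md$transcript_id) else rep(NA_character_, length(gr))

  feat <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    geneId = as.character(md$gene_id),
    txId = txId,
    stringsAsFactors = FALSE
  )
  feat$name <- if ("gene_name" %in% colnames(md)) as.character(md$gene_name) else feat$geneId
  feat$description <- if ("description" %in% colnames(md)) as.character(md$description) else ""
  feat$biotype <- if ("transcript_biotype" %in% colnames(md))
    as.character(md$transcript_biotype)
  else if ("gene_biotype" %in% colnames(md))
    as.character(md$gene_biotype)
  else "protein_coding"

  nBadContig <- 0L
  nBadCds <- 0L

  txRows <- feat[feat$type %in% c("exon", "CDS", "start_codon", "stop_codon", "transcript") &
                   !is.na(feat$txId), , drop = FALSE]
  txs <- list()
  for (tid in unique(txRows$txId)) {
    rows <- txRows[txRows$txId == tid, , drop = FALSE]
    contig <- rows$contig[1]
    if (!contig %in% names(genome)) {
      nBadContig <- nBadContig + 1L
      next
    }
    strand <- rows$strand[1]
    exr <- rows[rows$type == "exon", , drop = FALSE]
    exr <- exr[order(exr$start), , drop = FALSE]
    cdr <- rows[rows$type == "CDS", , drop = FALSE]
    cdr <- cdr[order(cdr$start), , drop = FALSE]
    exons <- IRanges::IRanges(start = exr$start, end = exr$end)
    cds <- IRanges::IRanges(start = cdr$start, end = cdr$end)

    hasStartFeat <- any(rows$type == "start_codon")
    stopRows <- rows[rows$type == "stop_codon", , drop = FALSE]
    hasStopFeat <- nrow(stopRows) > 0

    if (length(cds) > 0 && hasStopFeat) {
      # merge stop codon into CDS unless already covered
      for (i in seq_len(nrow(stopRows))) {
        covered <- any(stopRows$start[i] >= IRanges::start(cds) &
                         stopRows$end[i] <= IRanges::end(cds))
        if (!covered)
          cds <- c(cds, IRanges::IRanges(stopRows$start[i], stopRows$end[i]))
      }
      cds <- IRanges::reduce(cds)
    }

    # containment check before constructing (validity would also catch it)
    ok <- TRUE
    if (length(cds) > 0 && length(exons) > 0) {
      contained <- vapply(seq_along(cds), function(i) {
        any(IRanges::start(cds)[i] >= IRanges::start(exons) &
              IRanges::end(cds)[i] <= IRanges::end(exons))
      }, logical(1))
      ok <- all(contained)
    }
    if (!ok) {
      nBadCds <- nBadCds + 1L
      next
    }

    tx <- new("TranscriptModel",
      txId = tid, geneId = rows$geneId[1], contig = contig, strand = strand,
      exons = exons, cds = cds,
      hasStart = FALSE, hasStop = FALSE,
      biotype = rows$biotype[1])

    if (length(cds) > 0) {
      cdsSeq <- splicedSequence(tx, genome, "cds")
      tx@hasStart <- if (hasStartFeat) TRUE else startsWith(cdsSeq, "ATG")
      tx@hasStop <- if (hasStopFeat) TRUE else
        substring(cdsSeq, nchar(cdsSeq) - 2, nchar(cdsSeq)) %in% .STOP_CODONS
    }
    txs[[tid]] <- tx
  }

  if (nBadContig > 0 || nBadCds > 0)
    warning(sprintf("excluded %d transcript(s) on contigs absent from the genome and %d with CDS outside exons",
                    nBadContig, nBadCds))

  geneRows <- feat[feat$type == "gene", , drop = FALSE]
  byGene <- split(txs, vapply(txs, function(t) t@geneId, character(1)))
  geneIds <- sort(unique(c(geneRows$geneId, names(byGene))))
  genes <- list()
  for (gid in geneIds) {
    gtxs <- if (gid %in% names(byGene)) byGene[[gid]] else list()
    grow <- geneRows[geneRows$geneId == gid, , drop = FALSE]
    if (nrow(grow) == 0 && length(gtxs) == 0) next
    if (nrow(grow) > 0 && !grow$contig[1] %in% names(genome)) next
    contig <- if (nrow(grow) > 0) grow$contig[1] else gtxs[[1]]@contig
    strand <- if (nrow(grow) > 0) grow$strand[1] else gtxs[[1]]@strand
    exStarts <- unlist(lapply(gtxs, function(t) IRanges::start(t@exons)))
    exEnds <- unlist(lapply(gtxs, function(t) IRanges::end(t@exons)))
    spanStart <- as.integer(min(c(grow$start, exStarts)))
    spanEnd <- as.integer(max(c(grow$end, exEnds)))
    genes[[gid]] <- new("GeneModel",
      geneId = gid,
      name = if (nrow(grow) > 0) grow$name[1] else gid,
      description = if (nrow(grow) > 0) grow$description[1] else "",
      contig = contig, strand = strand,
      spanStart = spanStart, spanEnd = spanEnd,
      transcripts = unname(gtxs))
  }
  genes <- genes[order(names(genes))]

  geneRanges <- GenomicRanges::GRanges(
    seqnames = vapply(genes, function(g) g@contig, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(genes, function(g) g@spanStart, integer(1)),
      end = vapply(genes, function(g) g@spanEnd, integer(1))),
    gene_id = names(genes))

  new("AnnotationIndex", genes = genes, geneRanges = geneRanges,
      contigs = names(genome))
}

#' Genes overlapping a genomic position
#'
#' @param index an [AnnotationIndex-class].
#' @param contig contig name (must be known to the index).
#' @param position 1-based genomic coordinate.
#' @return list of [GeneModel-class] whose span contains `position`, sorted by
#'   gene id; possibly empty.
#' @export
genesAt <- function(index, contig, position) {
  stopifnot(is(index, "AnnotationIndex"))
  if (!contig %in% index@contigs)
    stop("unknown contig: ", contig)
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(position, position))
  hits <- GenomicRanges::findOverlaps(q, index@geneRanges, ignore.strand = TRUE)
  ids <- sort(S4Vectors::mcols(index@geneRanges)$gene_id[S4Vectors::subjectHits(hits)])
  index@genes[ids]
}

#' Spliced transcript or CDS sequence
#'
#' Concatenates the transcript's exon (or CDS) intervals in genomic order and
#' reverse-complements the joined block for minus-strand transcripts, yielding
#' the sequence in transcript orientation. For a complete coding transcript
#' (`hasStart` and `hasStop` both set) the CDS sequence starts with `ATG` and
#' ends with a stop codon.
#'
#' @param tx a [TranscriptModel-class].
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @param which `"exons"` or `"cds"`.
#' @return a character scalar in transcript orientation.
#' @export
splicedSequence <- function(tx, genome, which = c("exons", "cds")) {
  which <- match.arg(which)
  iv <- if (which == "exons") tx@exons else tx@cds
  if (length(iv) == 0) return("")
  pieces <- vapply(seq_along(iv), function(i) {
    genomeSubseq(genome, tx@contig, IRanges::start(iv)[i], IRanges::end(iv)[i])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (tx@strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Coding transcripts of a gene
#'
#' @param gene a [GeneModel-class].
#' @return list of member [TranscriptModel-class] objects with non-empty CDS,
#'   sorted by transcript id.
#' @export
codingTranscripts <- function(gene) {
  txs <- Filter(function(t) length(t@cds) > 0, gene@transcripts)
  txs[order(vapply(txs, function(t) t@txId, character(1)))]
}
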