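## Deterministic synthetic fixtures: mini-genomes with Ensembl-style GTF
## annotation, fusion breakpoint sets with independently computed oracle
## proteins, caller-format files, and planted-motif labeled datasets.
##
## The oracle path deliberately avoids the package's annotation/builder code:
## it works on the generator's own truth tables with plain string arithmetic
## and seqinr translation, so agreement between the two paths is a real
## cross-check of splicing, strand handling and translation.

## uniform integer draw on [lo, hi] immune to sample()'s scalar expansion
.sampleInt <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

.senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.randomSenseCodons <- function(n) {
  if (n == 0) return(character(0))
  sample(.senseCodons(), n, replace = TRUE)
}

## one representative codon per residue, for reverse translation
.revCodonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  tapply(names(sense), sense, function(x) x[1])
}

.randomNt <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Genome specification for the fixture generator
#'
#' Defaults produce compact multi-gene genomes (contigs well under 100 kb)
#' that exercise multi-exon, multi-isoform and minus-strand structure while
#' keeping every downstream test fast. Alternative isoforms are built by
#' in-frame cassette exons (codon-aligned blocks inside the CDS), which
#' guarantees each isoform still starts with ATG, ends at the same stop and
#' contains no in-frame internal stop.
#'
#' @param nContigs number of contigs (named `chrS1`, `chrS2`, ...).
#' @param genesPerContig genes per contig.
#' @param transcriptsPerGene integer range (min, max) of isoforms per gene.
#' @param exonsPerTranscript integer range of exon counts for the full
#'   isoform.
#' @param cdsCodons integer range of CDS length in codons (including stop).
#' @param utrLength integer range of UTR lengths (nt), both sides.
#' @param intronLength integer range of intron lengths (nt).
#' @param intergenicGap integer range of gap lengths (nt) between genes.
#' @param minusFraction expected fraction of minus-strand genes.
#' @param seed integer seed; everything is deterministic given it.
#' @return a validated spec list.
#' @export
genomeSpec <- function(nContigs = 2L, genesPerContig = 4L,
                       transcriptsPerGene = c(1L, 3L),
                       exonsPerTranscript = c(2L, 5L),
                       cdsCodons = c(60L, 150L),
                       utrLength = c(10L, 60L),
                       intronLength = c(30L, 120L),
                       intergenicGap = c(200L, 600L),
                       minusFraction = 0.4, seed = 1L) {
  spec <- list(nContigs = as.integer(nContigs),
               genesPerContig = as.integer(genesPerContig),
               transcriptsPerGene = as.integer(transcriptsPerGene),
               exonsPerTranscript = as.integer(exonsPerTranscript),
               cdsCodons = as.integer(cdsCodons),
               utrLength = as.integer(utrLength),
               intronLength = as.integer(intronLength),
               intergenicGap = as.integer(intergenicGap),
               minusFraction = minusFraction, seed = as.integer(seed))
  ranges <- c("transcriptsPerGene", "exonsPerTranscript", "cdsCodons",
              "utrLength", "intronLength", "intergenicGap")
  for (nm in ranges) {
    r <- spec[[nm]]
    if (length(r) != 2 || any(r < 1) || r[1] > r[2])
      stop("spec range '", nm, "' must be a valid (min, max) pair of positive integers")
  }
  if (spec$utrLength[1] < 4)
    stop("utrLength minimum must be >= 4 so UTR breakpoint classes are samplable")
  if (spec$intergenicGap[1] < 20)
    stop("intergenicGap minimum must be >= 20 so intergenic breakpoints are samplable")
  # cassette exons (one per extra isoform) need room inside the CDS
  maxCassettes <- spec$transcriptsPerGene[2] - 1L
  if (spec$cdsCodons[1] < 10L + maxCassettes * 10L)
    stop("infeasible spec: cdsCodons too small for the requested isoform count")
  spec
}

## sample one gene's structure in mRNA ("forward construction") space
.sampleGene <- function(spec, geneId, geneName) {
  nTx <- .sampleInt(spec$transcriptsPerGene[1], spec$transcriptsPerGene[2])
  nCas <- nTx - 1L
  nCod <- .sampleInt(spec$cdsCodons[1], spec$cdsCodons[2])
  utr5 <- .sampleInt(spec$utrLength[1], spec$utrLength[2])
  utr3 <- .sampleInt(spec$utrLength[1], spec$utrLength[2])
  stopCodon <- sample(c("TAA", "TAG", "TGA"), 1)
  cds <- paste0("ATG", paste(.randomSenseCodons(nCod - 2L), collapse = ""),
                stopCodon)
  cdsLen <- 3L * nCod
  mrna <- paste0(.randomNt(utr5), cds, .randomNt(utr3))
  mLen <- nchar(mrna)

  # cassette codon blocks, disjoint, interior (codons 3 .. nCod-3)
  cassettes <- list()
  if (nCas > 0) {
    avail <- seq(3L, nCod - 3L)
    for (ci in seq_len(nCas)) {
      w <- sample(3:6, 1)
      ok <- avail[avail + w - 1L <= nCod - 3L]
      ok <- ok[vapply(ok, function(s) all(seq(s, s + w - 1L) %in% avail),
                      logical(1))]
      if (length(ok) == 0)
        stop("infeasible spec: no room left for cassette exons")
      s <- if (length(ok) == 1) ok else sample(ok, 1)
      cassettes[[ci]] <- c(s, s + w - 1L)
      # reserve the block plus one flanking codon each side
      avail <- setdiff(avail, seq(s - 1L, s + w))
    }
  }

  # exon boundaries: cuts after these mRNA positions
  cuts <- integer(0)
  casNt <- lapply(cassettes, function(cc)
    c(utr5 + 3L * (cc[1] - 1L) + 1L, utr5 + 3L * cc[2]))
  for (cn in casNt) cuts <- c(cuts, cn[1] - 1L, cn[2])
  forbidden <- c(seq(utr5 + 1L, utr5 + 2L),                  # inside ATG
                 seq(utr5 + cdsLen - 2L, utr5 + cdsLen - 1L)) # inside stop
  for (cn in casNt) forbidden <- c(forbidden, seq(cn[1], cn[2] - 1L))
  nExonTarget <- max(.sampleInt(spec$exonsPerTranscript[1],
                                spec$exonsPerTranscript[2]),
                     length(cuts) + 1L)
  nExtra <- nExonTarget - 1L - length(cuts)
  if (nExtra > 0) {
    pool <- setdiff(seq_len(mLen - 1L), c(cuts, forbidden))
    nExtra <- min(nExtra, length(pool))
    if (nExtra > 0) cuts <- c(cuts, sample(pool, nExtra))
  }
  cuts <- sort(unique(cuts))
  segStarts <- c(1L, cuts + 1L)
  segEnds <- c(cuts, mLen)
  segs <- data.frame(mStart = segStarts, mEnd = segEnds)

  # which segment is each cassette?
  casSeg <- vapply(casNt, function(cn)
    which(segs$mStart == cn[1] & segs$mEnd == cn[2]), integer(1))

  strand <- if (stats::runif(1) < spec$minusFraction) "-" else "+"
  list(geneId = geneId, name = geneName, nTx = nTx, mrna = mrna,
       utr5 = utr5, utr3 = utr3, cdsLen = cdsLen, segs = segs,
       casSeg = casSeg, strand = strand,
       intronLens = .sampleInt(spec$intronLength[1], spec$intronLength[2],
                               nrow(segs) - 1L))
}

## lay a sampled gene onto genomic coordinates starting at g0 (1-based);
## returns forward genomic string + per-transcript truth records
.placeGene <- function(g, contig, g0) {
  segs <- g$segs
  nSeg <- nrow(segs)
  fStart <- integer(nSeg); fEnd <- integer(nSeg)
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_len(nSeg)) {
    seg <- substring(g$mrna, segs$mStart[i], segs$mEnd[i])
    fStart[i] <- cursor + 1L
    cursor <- cursor + nchar(seg)
    fEnd[i] <- cursor
    pieces <- c(pieces, seg)
    if (i < nSeg) {
      intr <- .randomNt(g$intronLens[i])
      pieces <- c(pieces, intr)
      cursor <- cursor + nchar(intr)
    }
  }
  forward <- paste(pieces, collapse = "")
  Lg <- nchar(forward)
  if (g$strand == "+") {
    gS <- g0 + fStart - 1L
    gE <- g0 + fEnd - 1L
    contigSeq <- forward
  } else {
    gS <- g0 + Lg - fEnd
    gE <- g0 + Lg - fStart
    contigSeq <- .revcompString(forward)
  }

  # per-transcript truth: transcript k = 1 keeps all segments; transcript
  # k >= 2 drops cassette segment k-1
  txs <- list()
  for (k in seq_len(g$nTx)) {
    keep <- seq_len(nSeg)
    if (k > 1) keep <- setdiff(keep, g$casSeg[k - 1L])
    mLens <- segs$mEnd[keep] - segs$mStart[keep] + 1L
    tEnd <- cumsum(mLens)
    tStart <- tEnd - mLens + 1L
    exons <- data.frame(gStart = gS[keep], gEnd = gE[keep],
                        tStart = tStart, tEnd = tEnd,
                        mStart = segs$mStart[keep], mEnd = segs$mEnd[keep])
    mrnaK <- paste(substring(g$mrna, segs$mStart[keep], segs$mEnd[keep]),
                   collapse = "")
    casLen <- if (k > 1) segs$mEnd[g$casSeg[k - 1L]] -
                           segs$mStart[g$casSeg[k - 1L]] + 1L else 0L
    cdsLenK <- g$cdsLen - casLen
    txId <- sprintf("%s.t%d", g$geneId, k)
    cdsNt <- substring(mrnaK, g$utr5 + 1L, g$utr5 + cdsLenK)
    txs[[txId]] <- list(txId = txId, geneId = g$geneId, contig = contig,
                        strand = g$strand, exons = exons, mrna = mrnaK,
                        utr5Len = g$utr5, cdsLen = cdsLenK,
                        protein = .oracleTranslateCds(cdsNt))
  }
  list(forwardLen = Lg, contigSeq = contigSeq, gStart = g0,
       gEnd = g0 + Lg - 1L, txs = txs)
}

.revcompString <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

## seqinr-based translation of a CDS (including stop); drops the trailing stop
.oracleTranslateCds <- function(nt) {
  aa <- .oracleTranslate(nt)
  sub("\\*$", "", aa)
}

#' Translate a nucleotide string (oracle path)
#'
#' Frame-0 translation via `seqinr::translate`, independent of the
#' Biostrings-based path used by the fusion builder. Stop codons appear as
#' `*`; ambiguous codons as `X`.
#'
#' @param nt nucleotide string.
#' @return amino-acid string (length `floor(nchar(nt) / 3)`).
#' @export
oracleTranslate <- function(nt) .oracleTranslate(nt)

.oracleTranslate <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  aa <- seqinr::translate(strsplit(substring(nt, 1, 3 * n), "",
                                   fixed = TRUE)[[1]], ambiguous = FALSE)
  paste(aa, collapse = "")
}

#' Generate a synthetic genome with annotation
#'
#' Writes a FASTA and an Ensembl-dialect GTF (gene / transcript / exon / CDS
#' / start_codon / stop_codon features, with the stop codon excluded from CDS
#' features per the Ensembl convention) and returns truth tables listing
#' every gene, transcript, exon layout and protein. Byte-identical output for
#' a given spec.
#'
#' @param spec a [genomeSpec()].
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gtf` (paths) and `truth` (list with
#'   `contigs`, `gaps`, `genes`, `transcripts`).
#' @export
makeGenome <- function(spec, dir = tempfile("synthgenome")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(spec$seed, {
    contigSeqs <- character(0)
    gaps <- list()
    genes <- list()
    txs <- list()
    geneCounter <- 0L
    for (ci in seq_len(spec$nContigs)) {
      contig <- sprintf("chrS%d", ci)
      pieces <- character(0)
      cursor <- 0L
      contigGaps <- list()
      for (gi in seq_len(spec$genesPerContig)) {
        gapLen <- .sampleInt(spec$intergenicGap[1], spec$intergenicGap[2])
        contigGaps[[length(contigGaps) + 1L]] <-
          c(cursor + 1L, cursor + gapLen)
        pieces <- c(pieces, .randomNt(gapLen))
        cursor <- cursor + gapLen
        geneCounter <- geneCounter + 1L
        geneId <- sprintf("ENSSYNG%08d", geneCounter)
        geneName <- sprintf("SYN%d", geneCounter)
        g <- .sampleGene(spec, geneId, geneName)
        placed <- .placeGene(g, contig, cursor + 1L)
        pieces <- c(pieces, placed$contigSeq)
        cursor <- cursor + placed$forwardLen
        genes[[geneId]] <- list(
          geneId = geneId, name = geneName,
          description = sprintf("synthetic gene %d", geneCounter),
          contig = contig, strand = g$strand,
          gStart = placed$gStart, gEnd = placed$gEnd,
          txIds = names(placed$txs))
        txs <- c(txs, placed$txs)
      }
      gapLen <- .sampleInt(spec$intergenicGap[1], spec$intergenicGap[2])
      contigGaps[[length(contigGaps) + 1L]] <- c(cursor + 1L, cursor + gapLen)
      pieces <- c(pieces, .randomNt(gapLen))
      contigSeqs[[contig]] <- paste(pieces, collapse = "")
      gaps[[contig]] <- do.call(rbind, contigGaps)
    }
    truth <- list(contigs = vapply(contigSeqs, nchar, integer(1)),
                  gaps = gaps, genes = genes, transcripts = txs,
                  seed = spec$seed)
    fasta <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    .writeFasta(contigSeqs, fasta)
    .writeGtf(truth, gtf)
    list(fasta = fasta, gtf = gtf, truth = truth)
  })
}

.writeFasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq.int(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

## map an mRNA sub-interval of one exon row to genomic coordinates
.mrnaToGenomic <- function(exon, strand, a, b) {
  if (strand == "+") {
    c(exon$gStart + (a - exon$mStart), exon$gStart + (b - exon$mStart))
  } else {
    c(exon$gEnd - (b - exon$mStart), exon$gEnd - (a - exon$mStart))
  }
}

.writeGtf <- function(truth, path) {
  attrStr <- function(...) {
    kv <- list(...)
    paste(vapply(names(kv), function(k)
      sprintf('%s "%s";', k, kv[[k]]), character(1)), collapse = " ")
  }
  lines <- character(0)
  addLine <- function(contig, feature, start, end, strand, attrs) {
    lines[[length(lines) + 1L]] <<- paste(contig, "synthgen", feature,
                                          start, end, ".", strand, ".",
                                          attrs, sep = "\t")
  }
  for (g in truth$genes) {
    gAttr <- attrStr(gene_id = g$geneId, gene_name = g$name,
                     gene_biotype = "protein_coding",
                     description = g$description)
    addLine(g$contig, "gene", g$gStart, g$gEnd, g$strand, gAttr)
    for (txId in g$txIds) {
      tx <- truth$transcripts[[txId]]
      tAttr <- attrStr(gene_id = g$geneId, transcript_id = txId,
                       gene_name = g$name,
                       gene_biotype = "protein_coding",
                       transcript_biotype = "protein_coding",
                       description = g$description)
      addLine(g$contig, "transcript", min(tx$exons$gStart),
              max(tx$exons$gEnd), g$strand, tAttr)
      ex <- tx$exons[order(tx$exons$gStart), , drop = FALSE]
      for (i in seq_len(nrow(ex)))
        addLine(g$contig, "exon", ex$gStart[i], ex$gEnd[i], g$strand, tAttr)
      # CDS (stop codon excluded), start_codon, stop_codon; bounds live in
      # transcript-local coordinates, so intersect in t-space and shift to
      # the exon's full-mRNA frame before the genomic mapping
      cdsA <- tx$utr5Len + 1L
      cdsB <- tx$utr5Len + tx$cdsLen - 3L
      stopA <- tx$utr5Len + tx$cdsLen - 2L
      stopB <- tx$utr5Len + tx$cdsLen
      emit <- function(exi, a, b, feature) {
        am <- exi$mStart + (a - exi$tStart)
        bm <- exi$mStart + (b - exi$tStart)
        gg <- .mrnaToGenomic(exi, tx$strand, am, bm)
        addLine(g$contig, feature, gg[1], gg[2], g$strand, tAttr)
      }
      for (i in seq_len(nrow(tx$exons))) {
        exi <- tx$exons[i, ]
        a <- max(exi$tStart, cdsA); b <- min(exi$tEnd, cdsB)
        if (a <= b) emit(exi, a, b, "CDS")
        a <- max(exi$tStart, cdsA); b <- min(exi$tEnd, cdsA + 2L)
        if (a <= b && a == cdsA && b == cdsA + 2L)
          emit(exi, a, b, "start_codon")
        a <- max(exi$tStart, stopA); b <- min(exi$tEnd, stopB)
        if (a <= b && a == stopA && b == stopB)
          emit(exi, a, b, "stop_codon")
      }
    }
  }
  writeLines(unlist(lines), path)
  invisible(path)
}

## ---- oracle fused-protein computation -------------------------------------

## locate a genomic position against a truth transcript (plain arithmetic)
.oracleLocate <- function(tx, gpos) {
  ex <- tx$exons
  for (i in seq_len(nrow(ex))) {
    if (gpos >= ex$gStart[i] && gpos <= ex$gEnd[i]) {
      t <- if (tx$strand == "+") ex$tStart[i] + (gpos - ex$gStart[i])
           else ex$tStart[i] + (ex$gEnd[i] - gpos)
      return(list(region = "exonic", t = t, exon = i))
    }
  }
  n <- nrow(ex)
  if (tx$strand == "+") {
    if (gpos < ex$gStart[1]) return(list(region = "upstream"))
    if (gpos > ex$gEnd[n]) return(list(region = "downstream"))
    after <- max(which(ex$gEnd < gpos))
  } else {
    if (gpos > ex$gEnd[1]) return(list(region = "upstream"))
    if (gpos < ex$gStart[n]) return(list(region = "downstream"))
    after <- max(which(ex$gStart > gpos))
  }
  list(region = "intronic", after = after)
}

#' Oracle fused protein for one transcript pair
#'
#' Independent reference computation over the generator's truth tables:
#' retained portions are found by plain arithmetic on the truth exon tables,
#' spliced with `substring`/`paste0`, and translated with seqinr. Shares no
#' code with [buildFusedTranscript()] / [translateFused()].
#'
#' @param truth truth tables from [makeGenome()].
#' @param tx5Id,tx3Id truth transcript ids.
#' @param bp5,bp3 genomic breakpoints (5': last retained base, 3': first
#'   retained base).
#' @return list with either `reason` or `sequence`, `junctionAA`, `inFrame`,
#'   `truncated`, `fivePrimeComplete`, `threePrimeComplete`.
#' @export
oracleFusedProtein <- function(truth, tx5Id, bp5, tx3Id, bp3) {
  tx5 <- truth$transcripts[[tx5Id]]
  tx3 <- truth$transcripts[[tx3Id]]
  cdsStart5 <- tx5$utr5Len + 1L
  cdsEnd5 <- tx5$utr5Len + tx5$cdsLen
  cdsStart3 <- tx3$utr5Len + 1L
  cdsEnd3 <- tx3$utr5Len + tx3$cdsLen
  stopStart3 <- cdsEnd3 - 2L

  loc5 <- .oracleLocate(tx5, bp5)
  t5 <- switch(loc5$region,
    exonic = loc5$t,
    upstream = 0L,
    downstream = nchar(tx5$mrna),
    intronic = tx5$exons$tEnd[loc5$after])
  if (t5 < cdsStart5 + 2L) return(list(reason = "no_cds_retained_5p"))

  loc3 <- .oracleLocate(tx3, bp3)
  t3 <- switch(loc3$region,
    exonic = loc3$t,
    upstream = 1L,
    downstream = nchar(tx3$mrna) + 1L,
    intronic = tx3$exons$tStart[loc3$after + 1L])
  if (t3 > stopStart3) return(list(reason = "no_cds_retained_3p"))

  part5 <- substring(tx5$mrna, cdsStart5, t5)
  part3 <- substring(tx3$mrna, t3, nchar(tx3$mrna))
  junction <- nchar(part5)
  fused <- paste0(part5, part3)

  aa <- .oracleTranslate(fused)
  stopPos <- regexpr("*", aa, fixed = TRUE)
  annotStopNt <- junction + (stopStart3 - t3 + 1L)
  if (stopPos < 0) {
    protein <- aa
    truncated <- TRUE
  } else {
    protein <- substring(aa, 1L, stopPos - 1L)
    truncated <- ((stopPos - 1L) * 3L + 1L) != annotStopNt
  }
  if (nchar(protein) == 0) return(list(reason = "too_short"))
  jcod <- junction %/% 3L + 1L
  junctionAA <- if (nchar(protein) >= jcod) jcod else nchar(protein) + 1L

  r <- max(t3, cdsStart3)
  inFrame <- ((junction + (r - t3 + 1L) - 1L) %% 3L) == ((r - cdsStart3) %% 3L)

  list(sequence = protein, junctionAA = junctionAA, inFrame = inFrame,
       truncated = truncated,
       fivePrimeComplete = t5 >= cdsEnd5,
       threePrimeComplete = t3 <= cdsStart3)
}

## map a transcript coordinate of a truth transcript to a genomic position
.oracleT2G <- function(tx, t) {
  ex <- tx$exons
  i <- which(t >= ex$tStart & t <= ex$tEnd)[1]
  if (tx$strand == "+") ex$gStart[i] + (t - ex$tStart[i])
  else ex$gEnd[i] - (t - ex$tStart[i])
}

## sample a transcript coordinate in [lo, hi] and return its genomic position
.sampleTxPos <- function(tx, lo, hi) {
  t <- if (lo >= hi) lo else .sampleInt(lo, hi)
  .oracleT2G(tx, t)
}

#' Generate fusion breakpoint cases with oracle expectations
#'
#' Samples `n` breakpoint pairs over a generated genome, cycling through the
#' requested breakpoint classes, and computes the expected outcome of every
#' coding transcript pair with the independent string oracle.
#'
#' Classes: `exonic` (both breakpoints inside CDS exons), `intronic` (5'
#' breakpoint inside an intron), `utr5` (5' breakpoint in the 5' UTR, so no
#' upstream CDS is retained), `post_stop_5p` (5' breakpoint after the stop
#' codon: upstream gene complete), `pre_start_3p` (3' breakpoint before the
#' start codon: downstream gene complete), `intergenic` (5' breakpoint in an
#' intergenic gap).
#'
#' @param truth truth tables from [makeGenome()].
#' @param n number of fusion cases.
#' @param classes character vector of class names cycled over the cases.
#' @param seed integer seed.
#' @return list of fusion-truth records: `chrom5`, `pos5`, `chrom3`, `pos3`,
#'   `class`, `gene5`, `gene3`, `expectedReason` (for empty sets) and
#'   `pairs` (list of per-transcript-pair oracle results).
#' @export
makeFusions <- function(truth, n, classes = c("exonic", "intronic"),
                        seed = 1L) {
  known <- c("exonic", "intronic", "utr5", "post_stop_5p", "pre_start_3p",
             "intergenic")
  bad <- setdiff(classes, known)
  if (length(bad))
    stop("unknown breakpoint class(es): ", paste(bad, collapse = ", "))
  geneIds <- names(truth$genes)
  if (length(geneIds) < 2)
    stop("need at least two genes to build fusions")
  multiExon <- geneIds[vapply(geneIds, function(gid) {
    nrow(truth$transcripts[[truth$genes[[gid]]$txIds[1]]]$exons) > 1
  }, logical(1))]

  .withSeed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- classes[(i - 1L) %% length(classes) + 1L]
      if (cls == "intronic" && length(multiExon) == 0)
        stop("class 'intronic' impossible: no multi-exon gene in this genome")
      g5id <- if (cls == "intronic") sample(multiExon, 1) else sample(geneIds, 1)
      g3id <- sample(setdiff(geneIds, g5id), 1)
      g5 <- truth$genes[[g5id]]; g3 <- truth$genes[[g3id]]
      tx5 <- truth$transcripts[[g5$txIds[1]]]  # full isoform
      tx3 <- truth$transcripts[[g3$txIds[1]]]
      cdsStart5 <- tx5$utr5Len + 1L
      cdsEnd5 <- tx5$utr5Len + tx5$cdsLen
      cdsStart3 <- tx3$utr5Len + 1L
      stopStart3 <- tx3$utr5Len + tx3$cdsLen - 2L

      # default: exonic CDS-interior positions on both sides
      pos5 <- .sampleTxPos(tx5, cdsStart5 + 3L, cdsEnd5 - 4L)
      pos3 <- .sampleTxPos(tx3, cdsStart3 + 3L, stopStart3 - 1L)
      expectedReason <- ""
      if (cls == "intronic") {
        ex <- tx5$exons
        j <- if (nrow(ex) == 2) 1L else sample(seq_len(nrow(ex) - 1L), 1)
        rng <- if (tx5$strand == "+") c(ex$gEnd[j] + 1L, ex$gStart[j + 1L] - 1L)
               else c(ex$gEnd[j + 1L] + 1L, ex$gStart[j] - 1L)
        pos5 <- if (rng[1] >= rng[2]) rng[1] else .sampleInt(rng[1], rng[2])
      } else if (cls == "utr5") {
        pos5 <- .sampleTxPos(tx5, 1L, tx5$utr5Len - 1L)
        expectedReason <- "no_cds_retained_5p"
      } else if (cls == "post_stop_5p") {
        pos5 <- .sampleTxPos(tx5, cdsEnd5 + 1L, nchar(tx5$mrna))
      } else if (cls == "pre_start_3p") {
        pos3 <- .sampleTxPos(tx3, 1L, tx3$utr5Len)
      } else if (cls == "intergenic") {
        gp <- truth$gaps[[g5$contig]]
        row <- gp[sample(nrow(gp), 1), ]
        pos5 <- .sampleInt(row[1] + 2L, row[2] - 2L)
        expectedReason <- "no_gene_at_breakpoint"
      }

      pairs <- list()
      if (cls != "intergenic") {
        for (t5id in g5$txIds) {
          for (t3id in g3$txIds) {
            res <- oracleFusedProtein(truth, t5id, pos5, t3id, pos3)
            res$tx5Id <- t5id; res$tx3Id <- t3id
            pairs[[length(pairs) + 1L]] <- res
          }
        }
      }
      out[[i]] <- list(chrom5 = g5$contig, pos5 = pos5,
                       chrom3 = g3$contig, pos3 = pos3,
                       class = cls, gene5 = g5id, gene3 = g3id,
                       expectedReason = expectedReason, pairs = pairs)
    }
    out
  })
}

#' Write fusion cases as generic and caller-style input files
#'
#' Emits, from one truth table, a generic N x 4 TSV, an N x 5 labeled TSV
#' (when labels are supplied) and a star-fusion-style file, enabling the
#' adapter-equivalence round trip.
#'
#' @param fusions list from [makeFusions()].
#' @param dir output directory.
#' @param labels optional 0/1 integer vector, one per fusion.
#' @return named list of file paths.
#' @export
writeFusionFiles <- function(fusions, dir, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  generic <- file.path(dir, "fusions.tsv")
  rows <- vapply(fusions, function(f)
    paste(f$chrom5, f$pos5, f$chrom3, f$pos3, sep = "\t"), character(1))
  writeLines(rows, generic)
  out <- list(generic = generic)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(fusions), all(labels %in% 0:1))
    labeledPath <- file.path(dir, "fusions_labeled.tsv")
    writeLines(paste(rows, labels, sep = "\t"), labeledPath)
    out$labeled <- labeledPath
  }
  caller <- file.path(dir, "fusions_starfusion.tsv")
  header <- paste("#FusionName", "JunctionReadCount", "SpanningFragCount",
                  "LeftBreakpoint", "RightBreakpoint", sep = "\t")
  callerRows <- vapply(seq_along(fusions), function(i) {
    f <- fusions[[i]]
    paste(paste0(f$gene5, "--", f$gene3), 10 + i, 5 + i,
          paste(f$chrom5, f$pos5, "+", sep = ":"),
          paste(f$chrom3, f$pos3, "+", sep = ":"), sep = "\t")
  }, character(1))
  writeLines(c(header, callerRows), caller)
  out$caller <- caller
  out
}

## ---- planted-motif labeled datasets ---------------------------------------

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.randomProtein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

#' Generate a planted-motif labeled protein dataset
#'
#' Positives carry `motif` at a uniformly random offset; negatives are
#' rejection-sampled so they never contain it as a substring. With
#' `breakpointBacked = TRUE` the dataset is additionally realized as a
#' synthetic genome plus an N x 5 labeled breakpoint file: each labeled
#' fusion joins a dedicated single-exon gene pair whose (unique, in-frame,
#' non-truncated) fused protein is exactly the labeled sequence.
#'
#' @param n number of sequences.
#' @param motif amino-acid k-mer (length >= 4, standard residues only).
#' @param posFraction fraction of positives in (0, 1).
#' @param lengthRange integer range of sequence lengths (residues).
#' @param seed integer seed.
#' @param breakpointBacked also emit genome + labeled breakpoint file.
#' @param dir output directory for breakpoint-backed files.
#' @return list with `sequences`, `labels`, `motifOffset` (NA for negatives)
#'   and, when breakpoint-backed, `fasta`, `gtf`, `labeledFile`, `truth`.
#' @export
makeLabeledDataset <- function(n, motif, posFraction = 0.5,
                               lengthRange = c(80L, 200L), seed = 1L,
                               breakpointBacked = FALSE,
                               dir = tempfile("synthlabeled")) {
  if (nchar(motif) < 4)
    stop("motif length must be >= 4")
  if (!all(strsplit(motif, "", fixed = TRUE)[[1]] %in% .AA20))
    stop("motif contains invalid residue(s)")
  if (posFraction <= 0 || posFraction >= 1)
    stop("posFraction must be in (0, 1)")
  nPos <- round(n * posFraction)
  mLen <- nchar(motif)
  .withSeed(seed, {
    labels <- c(rep(1L, nPos), rep(0L, n - nPos))
    seqs <- character(n)
    offs <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      len <- .sampleInt(lengthRange[1], lengthRange[2])
      if (labels[i] == 1L) {
        s <- .randomProtein(len)
        off <- sample(seq_len(len - mLen + 1L), 1)
        substring(s, off, off + mLen - 1L) <- motif
        # planting could in principle re-create the motif elsewhere; keep one
        seqs[i] <- s
        offs[i] <- off
      } else {
        repeat {
          s <- .randomProtein(len)
          if (!grepl(motif, s, fixed = TRUE)) break
        }
        seqs[i] <- s
      }
    }
    out <- list(sequences = seqs, labels = labels, motifOffset = offs)
    if (breakpointBacked) {
      # every sequence must start with M (translation starts at ATG) and be
      # unique so fusion-level labels survive protein deduplication
      seqs <- paste0("M", substring(seqs, 2L))
      seqs <- make.unique(seqs, sep = "")  # collisions are ~impossible
      out$sequences <- seqs
      bb <- .breakpointBackedGenome(seqs, labels, dir)
      out <- c(out, bb)
    }
    out
  })
}

## realize labeled proteins as single-exon gene pairs + breakpoints
.breakpointBackedGenome <- function(seqs, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  revTab <- .revCodonTable()
  toCodons <- function(aaStr) {
    aa <- strsplit(aaStr, "", fixed = TRUE)[[1]]
    unname(revTab[aa])
  }
  contig <- "chrSL1"
  pieces <- character(0)
  cursor <- 0L
  genes <- list(); txs <- list()
  rows <- character(length(seqs))
  gapLen <- 50L
  for (i in seq_along(seqs)) {
    cod <- toCodons(seqs[i])
    m <- length(cod)
    j <- max(2L, min(m - 2L, .sampleInt(2L, m - 2L)))
    utrA <- .randomNt(12L); utrB <- .randomNt(12L)
    # upstream gene: codons 1..j + spacer codons + stop
    extra <- .randomSenseCodons(5L)
    cdsA <- paste0(paste(cod[1:j], collapse = ""),
                   paste(extra, collapse = ""), "TAA")
    mrnaA <- paste0(utrA, cdsA, utrB)
    # downstream gene: ATG + filler codons + codons j+1..m + stop
    filler <- .randomSenseCodons(4L)
    cdsB <- paste0("ATG", paste(filler, collapse = ""),
                   paste(cod[(j + 1L):m], collapse = ""), "TAA")
    utrC <- .randomNt(12L); utrD <- .randomNt(12L)
    mrnaB <- paste0(utrC, cdsB, utrD)

    mk <- function(which, mrna, cdsLen, utr5) {
      gid <- sprintf("ENSSYNL%05d%s", i, which)
      g0 <- cursor + gapLen + 1L
      pieces <<- c(pieces, .randomNt(gapLen), mrna)
      cursor <<- cursor + gapLen + nchar(mrna)
      txId <- paste0(gid, ".t1")
      txs[[txId]] <<- list(
        txId = txId, geneId = gid, contig = contig, strand = "+",
        exons = data.frame(gStart = g0, gEnd = g0 + nchar(mrna) - 1L,
                           tStart = 1L, tEnd = nchar(mrna),
                           mStart = 1L, mEnd = nchar(mrna)),
        mrna = mrna, utr5Len = utr5, cdsLen = cdsLen,
        protein = .oracleTranslateCds(substring(mrna, utr5 + 1L,
                                                utr5 + cdsLen)))
      genes[[gid]] <<- list(geneId = gid, name = paste0("SYNL", i, which),
                            description = "synthetic labeled gene",
                            contig = contig, strand = "+",
                            gStart = g0, gEnd = g0 + nchar(mrna) - 1L,
                            txIds = txId)
      g0
    }
    g0A <- mk("A", mrnaA, nchar(cdsA), nchar(utrA))
    g0B <- mk("B", mrnaB, nchar(cdsB), nchar(utrC))
    bp5 <- g0A + nchar(utrA) + 3L * j - 1L          # last base of codon j
    bp3 <- g0B + nchar(utrC) + 3L + 12L             # first base of codon j+1
    rows[i] <- paste(contig, bp5, contig, bp3, labels[i], sep = "\t")
  }
  pieces <- c(pieces, .randomNt(gapLen))
  contigSeq <- paste(pieces, collapse = "")
  truth <- list(contigs = stats::setNames(nchar(contigSeq), contig),
                gaps = list(), genes = genes, transcripts = txs)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  .writeFasta(stats::setNames(list(contigSeq), contig), fasta)
  .writeGtf(truth, gtf)
  labeledFile <- file.path(dir, "labeled.tsv")
  writeLines(rows, labeledFile)
  list(fasta = fasta, gtf = gtf, labeledFile = labeledFile, truth = truth)
}
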