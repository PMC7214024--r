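# Hand-built fixtures small enough to reason about on paper.

`%||%` <- function(a, b) if (is.null(a)) b else a

# construct a TranscriptModel directly (coordinates 1-based inclusive)
makeTx <- function(txId, geneId, contig, strand, exons, cds,
                   hasStart = TRUE, hasStop = TRUE) {
  new("TranscriptModel", txId = txId, geneId = geneId, contig = contig,
      strand = strand,
      exons = IRanges::IRanges(start = exons[, 1], end = exons[, 2]),
      cds = IRanges::IRanges(start = cds[, 1], end = cds[, 2]),
      hasStart = hasStart, hasStop = hasStop, biotype = "protein_coding")
}

# Two single-exon plus-strand genes on one contig with fully known layout.
#
# gene U: 20 nt gap | utr5 "ACAC" (4) | CDS ATG GCC AAA GAA TTG TAA | utr3
#         "GGCCTT" (6)
# gene D: 20 nt gap | utr5 "ACACAC" (6) | CDS ATG CTA ACC GGG TAA | utr3
#         "CCGGA" (5)
#
# geneU CDS translates to MAKEL; geneD CDS to MLTG. geneD codon 2 is CTA, so
# a 3' breakpoint one base into it yields a retained portion starting "TAA"
# (an immediate engineered stop under a phase-preserving junction).
flagFixture <- function() {
  utr5U <- "ACAC"; cdsU <- "ATGGCCAAAGAATTGTAA"; utr3U <- "GGCCTT"
  utr5D <- "ACACAC"; cdsD <- "ATGCTAACCGGGTAA"; utr3D <- "CCGGA"
  gap <- strrep("T", 20)
  geneUseq <- paste0(utr5U, cdsU, utr3U)
  geneDseq <- paste0(utr5D, cdsD, utr3D)
  contig <- paste0(gap, geneUseq, gap, geneDseq, gap)
  genome <- Biostrings::DNAStringSet(c(chrT = contig))

  uStart <- 21L                      # gene U first base
  uCdsStart <- uStart + nchar(utr5U) # 25
  uEnd <- uStart + nchar(geneUseq) - 1L
  dStart <- uEnd + 20L + 1L
  dCdsStart <- dStart + nchar(utr5D)
  dEnd <- dStart + nchar(geneDseq) - 1L

  txU <- makeTx("TXU", "GU", "chrT", "+",
                cbind(uStart, uEnd),
                cbind(uCdsStart, uCdsStart + nchar(cdsU) - 1L))
  txD <- makeTx("TXD", "GD", "chrT", "+",
                cbind(dStart, dEnd),
                cbind(dCdsStart, dCdsStart + nchar(cdsD) - 1L))
  list(genome = genome, txU = txU, txD = txD,
       uStart = uStart, uCdsStart = uCdsStart, uEnd = uEnd,
       dStart = dStart, dCdsStart = dCdsStart, dEnd = dEnd,
       utr5U = utr5U, cdsU = cdsU, utr5D = utr5D, cdsD = cdsD)
}

# minimal synthetic result table for ranking/threshold tests
mkResults <- function(probs, rows = seq_along(probs) - 1L) {
  n <- length(probs)
  data.frame(
    fusionPair = paste0("A", seq_len(n), "_B", seq_len(n)),
    oncProb = probs,
    gene5Id = paste0("G", seq_len(n)), gene5Name = "a",
    gene5Description = "d", gene3Id = paste0("H", seq_len(n)),
    gene3Name = "b", gene3Description = "d",
    mainProteinLength = 10L, truncated = FALSE,
    fivePrimeComplete = FALSE, threePrimeComplete = FALSE,
    nCandidates = 1L, mainProtein = "MAAAAAAAAA",
    sourceRow = rows, reason = "", stringsAsFactors = FALSE)
}

# assemble an AnnotationIndex directly from GeneModel objects
makeGene <- function(geneId, name, contig, strand, txs,
                     description = "hand-built gene") {
  spanStart <- min(vapply(txs, function(t) min(IRanges::start(t@exons)),
                          integer(1)))
  spanEnd <- max(vapply(txs, function(t) max(IRanges::end(t@exons)),
                        integer(1)))
  new("GeneModel", geneId = geneId, name = name, description = description,
      contig = contig, strand = strand, spanStart = spanStart,
      spanEnd = spanEnd, transcripts = txs)
}

makeIndex <- function(genes, contigs) {
  genes <- genes[order(vapply(genes, function(g) g@geneId, character(1)))]
  names(genes) <- vapply(genes, function(g) g@geneId, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(genes, function(g) g@contig, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(genes, function(g) g@spanStart, integer(1)),
      end = vapply(genes, function(g) g@spanEnd, integer(1))),
    gene_id = names(genes))
  new("AnnotationIndex", genes = genes, geneRanges = gr, contigs = contigs)
}

# compare one builder candidate row against one oracle record
expectCandidateMatchesOracle <- function(p, e) {
  expect_identical(p$sequence, e$sequence)
  expect_identical(p$junctionAA, as.integer(e$junctionAA))
  expect_identical(p$truncated, e$truncated)
  expect_identical(p$inFrame, e$inFrame)
  expect_identical(p$fivePrimeComplete, e$fivePrimeComplete)
  expect_identical(p$threePrimeComplete, e$threePrimeComplete)
}

# sort + dedup oracle pair records the way the builder does
oracleExpectedSet <- function(pairs) {
  exp <- Filter(function(p) is.null(p$reason), pairs)
  if (length(exp) == 0) return(exp)
  ord <- order(vapply(exp, `[[`, "", "tx5Id"), vapply(exp, `[[`, "", "tx3Id"))
  exp <- exp[ord]
  exp[!duplicated(vapply(exp, `[[`, "", "sequence"))]
}

# count matched (fusion, transcript-pair) cases between builder and oracle;
# stops the test early on any disagreement
checkFusionsAgainstOracle <- function(fusions, index, genome) {
  nCases <- 0L
  for (f in fusions) {
    sets <- enumerateCandidates(
      list(chrom5 = f$chrom5, pos5 = f$pos5,
           chrom3 = f$chrom3, pos3 = f$pos3), index, genome)
    if (f$class == "intergenic") {
      expect_identical(sets[[1]]@reason, "no_gene_at_breakpoint")
      nCases <- nCases + 1L
      next
    }
    expect_length(sets, 1L)
    cs <- sets[[1]]
    exp <- oracleExpectedSet(f$pairs)
    expect_equal(nrow(cs@proteins), length(exp))
    for (k in seq_along(exp))
      expectCandidateMatchesOracle(cs@proteins[k, ], exp[[k]])
    # skipped transcript pairs must carry the oracle's reason codes
    skips <- Filter(function(p) !is.null(p$reason), f$pairs)
    for (s in skips) {
      hit <- cs@skipped$reason[cs@skipped$tx5Id == s$tx5Id &
                                 cs@skipped$tx3Id == s$tx3Id]
      expect_identical(hit, s$reason)
    }
    nCases <- nCases + length(f$pairs)
  }
  nCases
}
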