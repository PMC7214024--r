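# The flagFixture layout (see helper-fixtures.R):
#   gene U (chrT:21-48, +): utr5 4 nt, CDS ATG GCC AAA GAA TTG TAA -> MAKEL
#   gene D (chrT:69-94, +): utr5 6 nt, CDS ATG CTA ACC GGG TAA -> MLTG

test_that("translateFused implements stop-aware standard-code translation", {
  r <- translateFused("ATGGCTTAA", 6L, 7L)
  expect_identical(r$sequence, "MA")
  expect_false(r$truncated)
  expect_identical(r$junctionAA, 3L)   # translation consumed the junction

  r <- translateFused("ATGTAAGGGCCC", 9L, 100L)
  expect_identical(r$sequence, "M")
  expect_true(r$truncated)
  expect_identical(r$junctionAA, 2L)   # length + 1: stopped before junction

  # codons containing N become X
  r <- translateFused("ATGANTTAA", 3L, 7L)
  expect_identical(r$sequence, "MX")
  expect_false(r$truncated)

  # no stop at all
  r <- translateFused("ATGGCTGCT", 3L, NA_integer_)
  expect_identical(r$sequence, "MAA")
  expect_true(r$truncated)

  expect_identical(translateFused("AT", 0L, NA_integer_)$reason, "too_short")
})

test_that("in-frame junction with no introduced stop is not truncated", {
  fx <- flagFixture()
  b <- buildFusedTranscript(fx$txU, 33L, fx$txD, 78L, fx$genome)
  expect_identical(b$junctionOffset, 9L)
  expect_true(b$inFrame)
  tr <- translateFused(b$fused, b$junctionOffset, b$stopOffset)
  expect_identical(tr$sequence, "MAKLTG")
  expect_false(tr$truncated)
  expect_identical(tr$junctionAA, 4L)
  expect_false(b$fivePrimeComplete)
  expect_false(b$threePrimeComplete)
  # retained 5' codons (3) + retained 3' codons (3) = protein length
  expect_identical(nchar(tr$sequence), 6L)
})

test_that("frameshifted junction with engineered early stop is truncated", {
  fx <- flagFixture()
  # one base into gene D codon 2 puts TAA immediately after the junction
  b <- buildFusedTranscript(fx$txU, 33L, fx$txD, 79L, fx$genome)
  expect_false(b$inFrame)
  tr <- translateFused(b$fused, b$junctionOffset, b$stopOffset)
  expect_identical(tr$sequence, "MAK")
  expect_true(tr$truncated)
  expect_identical(tr$junctionAA, 4L)  # length + 1
})

test_that("breakpoint after the 5' stop codon gives fivePrimeComplete", {
  fx <- flagFixture()
  b <- buildFusedTranscript(fx$txU, 45L, fx$txD, 78L, fx$genome)
  expect_true(b$fivePrimeComplete)
  expect_false(b$threePrimeComplete)
  tr <- translateFused(b$fused, b$junctionOffset, b$stopOffset)
  # translation ends at gene U's own stop: not gene D's annotated stop
  expect_identical(tr$sequence, "MAKEL")
  expect_true(tr$truncated)
  fl <- completenessFlags(fx$txU, 45L, fx$txD, 78L)
  expect_true(fl[["fivePrimeComplete"]])
  expect_false(fl[["threePrimeComplete"]])
})

test_that("breakpoint before the 3' start codon gives threePrimeComplete", {
  fx <- flagFixture()
  b <- buildFusedTranscript(fx$txU, 33L, fx$txD, 69L, fx$genome)
  expect_true(b$threePrimeComplete)
  expect_false(b$fivePrimeComplete)
  tr <- translateFused(b$fused, b$junctionOffset, b$stopOffset)
  # 6 nt of retained 5' UTR keep the downstream CDS in frame here
  expect_identical(tr$sequence, "MAKTHMLTG")
  expect_false(tr$truncated)
  fl <- completenessFlags(fx$txU, 33L, fx$txD, 69L)
  expect_false(fl[["fivePrimeComplete"]])
  expect_true(fl[["threePrimeComplete"]])
  # both breakpoints inside CDS: neither gene complete
  fl2 <- completenessFlags(fx$txU, 33L, fx$txD, 78L)
  expect_false(any(fl2))
})

test_that("exon-boundary and intronic 5' breakpoints retain whole exons", {
  fx <- flagFixture()
  # two-exon isoform of gene U: exon1 21-33 (utr5 + MAK codons),
  # intron 34-39, exon2 40-48 (TAA + utr3); CDS = ATGGCCAAA + TAA
  txU2 <- makeTx("TXU2", "GU", "chrT", "+",
                 cbind(c(21L, 40L), c(33L, 48L)),
                 cbind(c(25L, 40L), c(33L, 42L)))
  bExact <- buildFusedTranscript(txU2, 33L, fx$txD, 78L, fx$genome)
  expect_identical(bExact$junctionOffset, 9L)
  bIntron <- buildFusedTranscript(txU2, 36L, fx$txD, 78L, fx$genome)
  expect_identical(bIntron$fused, bExact$fused)
  expect_identical(substr(bIntron$fused, 1, 9), "ATGGCCAAA")
})

test_that("breakpoints outside the usable CDS yield reason codes", {
  fx <- flagFixture()
  # 5' breakpoint upstream of the start codon
  expect_identical(
    buildFusedTranscript(fx$txU, 23L, fx$txD, 78L, fx$genome)$reason,
    "no_cds_retained_5p")
  # 3' breakpoint downstream of the stop codon
  expect_identical(
    buildFusedTranscript(fx$txU, 33L, fx$txD, 92L, fx$genome)$reason,
    "no_cds_retained_3p")
})

test_that("enumerateCandidates resolves genes, dedups and reports reasons", {
  fx <- flagFixture()
  # gene U carries two isoforms yielding the same fused protein
  txU2 <- makeTx("TXU2", "GU", "chrT", "+",
                 cbind(fx$uStart, fx$uEnd),
                 cbind(fx$uCdsStart, fx$uCdsStart + nchar(fx$cdsU) - 1L))
  gU <- makeGene("GU", "GENEU", "chrT", "+", list(fx$txU, txU2))
  gD <- makeGene("GD", "GENED", "chrT", "+", list(fx$txD))
  idx <- makeIndex(list(gU, gD), names(fx$genome))

  sets <- enumerateCandidates(
    list(chrom5 = "chrT", pos5 = 33, chrom3 = "chrT", pos3 = 78),
    idx, fx$genome)
  expect_length(sets, 1)
  cs <- sets[[1]]
  # two tx pairs, identical protein -> deduplicated to one
  expect_identical(nrow(cs@proteins), 1L)
  expect_identical(cs@proteins$sequence, "MAKLTG")
  expect_identical(cs@proteins$tx5Id, "TXU")  # (tx5Id, tx3Id) sort order

  # intergenic 5' breakpoint
  empty <- enumerateCandidates(
    list(chrom5 = "chrT", pos5 = 5, chrom3 = "chrT", pos3 = 78),
    idx, fx$genome)
  expect_identical(empty[[1]]@reason, "no_gene_at_breakpoint")

  # all transcript pairs skipped: reason propagated
  utr <- enumerateCandidates(
    list(chrom5 = "chrT", pos5 = 22, chrom3 = "chrT", pos3 = 78),
    idx, fx$genome)
  expect_identical(utr[[1]]@reason, "no_cds_retained_5p")
  expect_identical(nrow(utr[[1]]@skipped), 2L)

  expect_error(enumerateCandidates(
    list(chrom5 = "chrZ", pos5 = 5, chrom3 = "chrT", pos3 = 78),
    idx, fx$genome), "unknown contig")
})

test_that("builder agrees with the string oracle on randomized fixtures", {
  for (sd in c(21, 22)) {
    gen <- makeGenome(genomeSpec(seed = sd), withr::local_tempdir())
    genome <- loadGenome(gen$fasta)
    idx <- loadAnnotation(gen$gtf, genome)
    fus <- makeFusions(gen$truth, 15,
                       classes = c("exonic", "intronic", "utr5",
                                   "post_stop_5p", "pre_start_3p"),
                       seed = sd)
    n <- checkFusionsAgainstOracle(fus, idx, genome)
    expect_gte(n, 15)
  }
})

test_that("identical inputs give identical candidate tables", {
  gen <- makeGenome(genomeSpec(seed = 23), withr::local_tempdir())
  genome <- loadGenome(gen$fasta)
  idx <- loadAnnotation(gen$gtf, genome)
  f <- makeFusions(gen$truth, 1, classes = "exonic", seed = 4)[[1]]
  fus <- list(chrom5 = f$chrom5, pos5 = f$pos5,
              chrom3 = f$chrom3, pos3 = f$pos3)
  a <- enumerateCandidates(fus, idx, genome)[[1]]
  b <- enumerateCandidates(fus, idx, genome)[[1]]
  expect_identical(a@proteins, b@proteins)
  expect_false(anyDuplicated(a@proteins$sequence) > 0)
})
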