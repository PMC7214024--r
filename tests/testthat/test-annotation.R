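test_that("loadGenome uppercases, maps U to T and rejects duplicates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "acgu", ">chrB desc", "AANNTT"), fa)
  g <- loadGenome(fa)
  expect_identical(names(g), c("chrA", "chrB"))
  expect_identical(as.character(g[["chrA"]]), "ACGT")
  expect_identical(as.character(g[["chrB"]]), "AANNTT")

  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "ACGT", ">chrA", "TTTT"), fa2)
  expect_error(loadGenome(fa2), "duplicate contig")
  expect_error(loadGenome(tempfile()), "not found")
})

test_that("genomeSubseq is exact and never clips", {
  g <- Biostrings::DNAStringSet(c(chrA = "ACGTACGT"))
  expect_identical(genomeSubseq(g, "chrA", 2, 5), "CGTA")
  expect_identical(nchar(genomeSubseq(g, "chrA", 1, 8)), 8L)
  expect_error(genomeSubseq(g, "chrA", 0, 3), "out of range")
  expect_error(genomeSubseq(g, "chrA", 5, 9), "out of range")
  expect_error(genomeSubseq(g, "chrZ", 1, 2), "unknown contig")
})

test_that("GTF structural errors report the offending line", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", strrep("ACGT", 30)), fa)
  g <- loadGenome(fa)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "chrA\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id \"G1\";",
    "chrA\tsrc\texon\t1\t100"), gtf)
  expect_error(loadAnnotation(gtf, g), "line 2")
})

test_that("annotation round-trips the generator's truth tables", {
  gen <- makeGenome(genomeSpec(seed = 11), withr::local_tempdir())
  genome <- loadGenome(gen$fasta)
  idx <- loadAnnotation(gen$gtf, genome)
  truth <- gen$truth
  expect_identical(sort(names(idx@genes)), sort(names(truth$genes)))
  nTx <- sum(vapply(idx@genes, function(g) length(g@transcripts), integer(1)))
  expect_identical(nTx, length(truth$transcripts))

  # spliced CDS of every transcript translates to the truth protein
  for (tid in names(truth$transcripts)) {
    tr <- truth$transcripts[[tid]]
    gene <- idx@genes[[tr$geneId]]
    tx <- Filter(function(t) t@txId == tid, gene@transcripts)[[1]]
    cds <- splicedSequence(tx, genome, "cds")
    expect_true(startsWith(cds, "ATG"))
    expect_true(tx@hasStart && tx@hasStop)
    n <- nchar(cds)
    aa <- Biostrings::GENETIC_CODE[substring(cds, seq(1, n - 2, 3),
                                             seq(3, n, 3))]
    expect_identical(paste(aa[-length(aa)], collapse = ""), tr$protein)
    expect_identical(unname(aa[length(aa)]), "*")
  }

  # loading is deterministic
  idx2 <- loadAnnotation(gen$gtf, genome)
  expect_identical(names(idx2@genes), names(idx@genes))
  for (gid in names(idx@genes))
    expect_true(identical(idx@genes[[gid]], idx2@genes[[gid]]))
})

test_that("genesAt agrees with an exhaustive span scan", {
  gen <- makeGenome(genomeSpec(seed = 12), withr::local_tempdir())
  genome <- loadGenome(gen$fasta)
  idx <- loadAnnotation(gen$gtf, genome)
  spans <- do.call(rbind, lapply(idx@genes, function(g)
    data.frame(gid = g@geneId, contig = g@contig,
               s = g@spanStart, e = g@spanEnd)))
  set.seed(42)
  for (i in 1:1000) {
    contig <- sample(names(genome), 1)
    pos <- sample(length(genome[[contig]]), 1)
    expected <- sort(spans$gid[spans$contig == contig &
                                 spans$s <= pos & spans$e >= pos])
    got <- names(genesAt(idx, contig, pos))
    expect_identical(got %||% character(0), expected)
  }
  expect_error(genesAt(idx, "chrNope", 5), "unknown contig")
})

test_that("genesAt returns all genes when spans overlap", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", strrep("ACGT", 100)), fa)
  g <- loadGenome(fa)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "G1"; gene_name "N1";'
  attr2 <- 'gene_id "G2"; gene_name "N2";'
  writeLines(c(
    paste("chrA", "src", "gene", 10, 100, ".", "+", ".", attr1, sep = "\t"),
    paste("chrA", "src", "gene", 50, 200, ".", "-", ".", attr2, sep = "\t")),
    gtf)
  idx <- loadAnnotation(gtf, g)
  expect_identical(names(genesAt(idx, "chrA", 60)), c("G1", "G2"))
  expect_identical(names(genesAt(idx, "chrA", 20)), "G1")
  expect_length(genesAt(idx, "chrA", 300), 0)
})

test_that("splicedSequence matches a naive string oracle on both strands", {
  g <- Biostrings::DNAStringSet(c(chrA = "AACCGGTTACGTACGTAACC"))
  txP <- makeTx("TP", "GP", "chrA", "+", cbind(c(3, 11), c(6, 14)),
                cbind(3, 6))
  expect_identical(splicedSequence(txP, g, "exons"),
                   paste0(substr("AACCGGTTACGTACGTAACC", 3, 6),
                          substr("AACCGGTTACGTACGTAACC", 11, 14)))
  txM <- makeTx("TM", "GM", "chrA", "-", cbind(c(3, 11), c(6, 14)),
                cbind(3, 6))
  naive <- paste0(substr("AACCGGTTACGTACGTAACC", 3, 6),
                  substr("AACCGGTTACGTACGTAACC", 11, 14))
  revcomp <- paste(rev(strsplit(chartr("ACGT", "TGCA", naive), "")[[1]]),
                   collapse = "")
  expect_identical(splicedSequence(txM, g, "exons"), revcomp)
})

test_that("transcripts with CDS outside exons are excluded with a warning", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", strrep("ACGT", 100)), fa)
  g <- loadGenome(fa)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  a <- 'gene_id "G1"; transcript_id "T1";'
  writeLines(c(
    paste("chrA", "s", "gene", 1, 120, ".", "+", ".", a, sep = "\t"),
    paste("chrA", "s", "transcript", 1, 120, ".", "+", ".", a, sep = "\t"),
    paste("chrA", "s", "exon", 1, 50, ".", "+", ".", a, sep = "\t"),
    paste("chrA", "s", "CDS", 40, 80, ".", "+", ".", a, sep = "\t")), gtf)
  expect_warning(idx <- loadAnnotation(gtf, g), "CDS outside exons")
  expect_length(idx@genes[["G1"]]@transcripts, 0)
})
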