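test_that("generation is byte-identical under a fixed seed", {
  spec <- genomeSpec(nContigs = 1L, genesPerContig = 2L,
                     transcriptsPerGene = c(1L, 1L), seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- makeGenome(spec, d1)
  g2 <- makeGenome(spec, d2)
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$gtf), readLines(g2$gtf))
  f1 <- makeFusions(g1$truth, 6, seed = 3)
  f2 <- makeFusions(g2$truth, 6, seed = 3)
  expect_identical(f1, f2)
})

test_that("truth-table CDS always starts ATG, ends at a stop, no internal stop", {
  gen <- makeGenome(genomeSpec(seed = 15), withr::local_tempdir())
  for (tx in gen$truth$transcripts) {
    cds <- substring(tx$mrna, tx$utr5Len + 1L, tx$utr5Len + tx$cdsLen)
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- oracleTranslate(cds)
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_identical(substr(aa, 1, nchar(aa) - 1), tx$protein)
  }
})

test_that("strand mix approximates the configured fraction over many genes", {
  spec <- genomeSpec(nContigs = 10L, genesPerContig = 20L,
                     transcriptsPerGene = c(1L, 1L),
                     exonsPerTranscript = c(1L, 2L),
                     cdsCodons = c(40L, 60L), intergenicGap = c(20L, 40L),
                     minusFraction = 0.4, seed = 8)
  gen <- makeGenome(spec, withr::local_tempdir())
  frac <- mean(vapply(gen$truth$genes, function(g) g$strand == "-",
                      logical(1)))
  expect_gt(frac, 0.30)
  expect_lt(frac, 0.50)
})

test_that("generated files round-trip through the package parsers", {
  gen <- makeGenome(genomeSpec(seed = 16), withr::local_tempdir())
  genome <- expect_no_warning(loadGenome(gen$fasta))
  idx <- expect_no_warning(loadAnnotation(gen$gtf, genome))
  fus <- makeFusions(gen$truth, 8, seed = 2)
  files <- writeFusionFiles(fus, withr::local_tempdir(),
                            labels = rep(c(0L, 1L), 4))
  generic <- parseFusions(files$generic)
  labeled <- parseFusions(files$labeled, labeled = TRUE)
  caller <- parseCallerFusions(files$caller, "star-fusion")
  cols <- c("chrom5", "pos5", "chrom3", "pos3")
  expect_identical(generic[, cols], labeled[, cols])
  expect_identical(generic[, cols], caller[, cols])
  expect_identical(labeled$label, rep(c(0L, 1L), 4))
})

test_that("breakpoint classes produce their advertised outcomes", {
  gen <- makeGenome(genomeSpec(seed = 17), withr::local_tempdir())
  fus <- makeFusions(gen$truth, 12,
                     classes = c("post_stop_5p", "pre_start_3p",
                                 "intergenic", "utr5"), seed = 5)
  for (f in fus) {
    if (f$class == "intergenic") {
      expect_identical(f$expectedReason, "no_gene_at_breakpoint")
    } else if (f$class == "utr5") {
      expect_true(all(vapply(f$pairs, function(p)
        identical(p$reason, "no_cds_retained_5p"), logical(1))))
    } else if (f$class == "post_stop_5p") {
      built <- Filter(function(p) is.null(p$reason), f$pairs)
      expect_true(all(vapply(built, `[[`, logical(1),
                             "fivePrimeComplete")))
    } else if (f$class == "pre_start_3p") {
      built <- Filter(function(p) is.null(p$reason), f$pairs)
      expect_true(all(vapply(built, `[[`, logical(1),
                             "threePrimeComplete")))
    }
  }
  expect_error(makeFusions(gen$truth, 2, classes = "sideways", seed = 1),
               "unknown breakpoint class")
})

test_that("planted-motif datasets respect labels, rejection and uniformity", {
  motif <- "LWYRKD"
  ds <- makeLabeledDataset(100, motif, 0.5, c(50, 80), seed = 10)
  expect_identical(sum(ds$labels == 1L), 50L)
  expect_identical(sum(ds$labels == 0L), 50L)
  expect_true(all(grepl(motif, ds$sequences[ds$labels == 1L], fixed = TRUE)))
  expect_false(any(grepl(motif, ds$sequences[ds$labels == 0L], fixed = TRUE)))

  # offsets roughly uniform: fixed length so every offset is valid
  big <- makeLabeledDataset(1000, motif, 0.9, c(60, 60), seed = 11)
  offs <- big$motifOffset[big$labels == 1L]
  maxOff <- 60 - nchar(motif) + 1
  expect_gte(min(offs), 1)
  expect_lte(max(offs), maxOff)
  thirds <- table(cut(offs, breaks = c(0, maxOff / 3, 2 * maxOff / 3, maxOff)))
  expect_true(all(thirds > length(offs) / 3 * 0.7))

  expect_error(makeLabeledDataset(10, "LW", seed = 1), "length")
  expect_error(makeLabeledDataset(10, "LWYRK*", seed = 1), "invalid")
  expect_error(makeLabeledDataset(10, "LWYRKD", posFraction = 1, seed = 1),
               "posFraction")
})

test_that("breakpoint-backed datasets reconstruct to the labeled proteins", {
  bb <- makeLabeledDataset(6, "HWKDFY", 0.5, c(40, 70), seed = 12,
                           breakpointBacked = TRUE,
                           dir = withr::local_tempdir())
  genome <- loadGenome(bb$fasta)
  idx <- loadAnnotation(bb$gtf, genome)
  lab <- parseFusions(bb$labeledFile, labeled = TRUE)
  for (i in seq_len(nrow(lab))) {
    cs <- enumerateCandidates(as.list(lab[i, ]), idx, genome)[[1]]
    expect_identical(nrow(cs@proteins), 1L)
    expect_identical(cs@proteins$sequence, bb$sequences[i])
    expect_false(cs@proteins$truncated)
    expect_true(cs@proteins$inFrame)
  }
})

test_that("infeasible specs are rejected up front", {
  expect_error(genomeSpec(cdsCodons = c(12L, 20L),
                          transcriptsPerGene = c(1L, 3L)), "infeasible")
  expect_error(genomeSpec(utrLength = c(2L, 10L)), "utrLength")
  expect_error(genomeSpec(intergenicGap = c(5L, 10L)), "intergenicGap")
})
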