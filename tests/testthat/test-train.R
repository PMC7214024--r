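test_that("candidate proteins inherit their fusion's label", {
  bb <- makeLabeledDataset(10, "HWKDFY", 0.5, c(40, 80), seed = 3,
                           breakpointBacked = TRUE,
                           dir = withr::local_tempdir())
  genome <- loadGenome(bb$fasta)
  idx <- loadAnnotation(bb$gtf, genome)
  lab <- parseFusions(bb$labeledFile, labeled = TRUE)
  ds <- buildTrainingSet(lab, idx, genome)
  expect_s4_class(ds, "TrainingDataset")
  expect_identical(length(ds@sequences), 10L)
  expect_identical(ds@conflicts, 0L)
  # labels match the generator's truth exactly
  expect_setequal(ds@sequences[ds@labels == 1L],
                  bb$sequences[bb$labels == 1L])
  expect_setequal(ds@sequences[ds@labels == 0L],
                  bb$sequences[bb$labels == 0L])
})

test_that("sequences observed under both labels are dropped and counted", {
  bb <- makeLabeledDataset(4, "HWKDFY", 0.5, c(40, 60), seed = 4,
                           breakpointBacked = TRUE,
                           dir = withr::local_tempdir())
  genome <- loadGenome(bb$fasta)
  idx <- loadAnnotation(bb$gtf, genome)
  lab <- parseFusions(bb$labeledFile, labeled = TRUE)
  # duplicate the first fusion with the opposite label
  dup <- lab[1, ]
  dup$label <- 1L - dup$label
  dup$sourceRow <- nrow(lab)
  ds <- buildTrainingSet(rbind(lab, dup), idx, genome)
  expect_identical(ds@conflicts, 1L)
  expect_identical(length(ds@sequences), 3L)
  expect_false(bb$sequences[1] %in% ds@sequences)

  # fusions that build nothing at all are an error
  none <- lab[1, ]
  none$pos5 <- 2L  # intergenic
  expect_error(buildTrainingSet(none, idx, genome), "empty training set")
})

test_that("balancing down-samples the majority and conserves the minority", {
  ds <- new("TrainingDataset",
            sequences = paste0("M", sapply(1:40, function(i)
              paste(rep(LETTERS[(i %% 20) + 1], 4), collapse = ""), USE.NAMES = FALSE),
              seq_len(40)),
            labels = c(rep(1L, 30), rep(0L, 10)),
            provenance = rep("x", 40), conflicts = 0L)
  b <- balanceDataset(ds, seed = 2)
  expect_identical(sum(b@labels == 1L), 10L)
  expect_identical(sum(b@labels == 0L), 10L)
  # minority class kept exactly
  expect_setequal(b@sequences[b@labels == 0L],
                  ds@sequences[ds@labels == 0L])
  # determinism / seed sensitivity
  expect_identical(balanceDataset(ds, seed = 2)@sequences, b@sequences)
  expect_false(identical(balanceDataset(ds, seed = 3)@sequences,
                         b@sequences))
  # already balanced -> unchanged
  expect_identical(balanceDataset(b, seed = 9), b)
  single <- new("TrainingDataset", sequences = c("MA", "MC"),
                labels = c(1L, 1L), provenance = c("a", "b"),
                conflicts = 0L)
  expect_error(balanceDataset(single), "single-class")
})

test_that("training learns a small planted motif and round-trips its archive", {
  ds <- makeLabeledDataset(80, "WYKDHR", 0.5, c(30, 60), seed = 6)
  tds <- new("TrainingDataset", sequences = ds$sequences,
             labels = ds$labels, provenance = rep("synthetic", 80),
             conflicts = 0L)
  cfg <- modelConfig(embeddingDim = 8, convFilters = 16, convKernel = 7,
                     poolSize = 2, lstmUnits = 8, epochs = 10, seed = 2)
  enc <- encoderConfig(maxLen = 60)
  fit <- trainModel(tds, cfg, enc)
  expect_true(fit$report$epochsRun >= 1 && fit$report$epochsRun <= 10)
  expect_true(fit$report$valAUROC > 0.5)
  expect_true(fit$report$finalTrainLoss < log(2))  # below chance loss
  expect_identical(unname(fit$report$classCounts), c(40L, 40L))

  # archive reproduces the trainer's validation scores
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(fit$model, f)
  m2 <- loadModel(f)
  valIdx <- fusionDriveR:::.stratifiedSplit(tds@labels,
                                            cfg$validationSplit, cfg$seed)
  p2 <- scoreSequences(m2, tds@sequences[valIdx])
  expect_equal(p2, fit$report$valScores, tolerance = 1e-6)

  # training is reproducible under a fixed seed
  fit2 <- trainModel(tds, cfg, enc)
  expect_identical(fit2$report$valScores, fit$report$valScores)

  expect_error(trainModel(new("TrainingDataset",
                              sequences = c("MA", "MK"),
                              labels = c(0L, 1L),
                              provenance = c("a", "b"), conflicts = 0L),
                          cfg, enc), "at least 20")
})

test_that("the AUROC helper agrees with the Wilcoxon statistic", {
  set.seed(9)
  y <- rep(c(0, 1), each = 30)
  p <- runif(60) + y * 0.3
  w <- wilcox.test(p[y == 1], p[y == 0])$statistic
  expect_equal(fusionDriveR:::.auroc(y, p), unname(w) / (30 * 30),
               tolerance = 1e-12)
})
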