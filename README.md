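# fusionDriveR

Prioritization of gene fusions by deep scoring of the chimeric proteins they
encode.

Fusion-detection tools running on RNA-seq emit long candidate lists in which
oncogenic driver fusions are buried among passengers. `fusionDriveR` ranks
them from sequence alone: given a genome (FASTA), an Ensembl-style annotation
(GTF) and, per fusion, just the chromosome and coordinate of the 5' and 3'
breakpoints, it

1. reconstructs **every** candidate fused protein — one attempt per pair of
   coding transcripts of the genes at the two breakpoints, translated from
   the upstream gene's start codon to the first stop;
2. scores each amino-acid sequence with a learned classifier
   (embedding → 1-D convolution → bidirectional LSTM → sigmoid);
3. aggregates the per-protein scores into the fusion's **oncogenic
   probability**

   `P(fusion) = max{ score(protein_1), ..., score(protein_m) }`

   so one convincing protein suffices to flag a fusion; and
4. writes a ranked report with gene information and per-protein flags:
   whether the protein is truncated (an early stop codon), and whether the
   5' gene's stop codon / 3' gene's start codon survive in the fusion. A
   threshold `thr` (default 0.8) defines the relevant subset via
   `P ≥ thr`.

A **retraining mode** fits a fresh model from an N×5 file (breakpoints plus a
0/1 oncogenicity label): every candidate protein inherits its fusion's label,
classes are balanced by down-sampling, and the trained network is written as
a single self-contained JSON archive that the inference mode loads back. A
deterministic **fixture generator** (`makeGenome()`, `makeFusions()`,
`makeLabeledDataset()`) builds mini-genomes, breakpoint sets with
independently computed oracle proteins, and planted-motif labeled datasets,
so the entire workflow is testable offline.

## Worked example

Train a model on a planted-motif labeled dataset (600 sequences, balanced,
motif `HWKDFY` in the positives), then run inference on eight fusions from a
breakpoint-backed fixture in which four fused proteins contain the motif:

```r
library(fusionDriveR)

ds  <- makeLabeledDataset(600, "HWKDFY", 0.5, c(80, 200), seed = 1)
tds <- new("TrainingDataset", sequences = ds$sequences, labels = ds$labels,
           provenance = rep("synthetic", 600), conflicts = 0L)
fit <- trainModel(tds, modelConfig(seed = 1, epochs = 20),
                  encoderConfig(maxLen = 200))
#> epochs 20, val AUROC 1.000
saveModel(fit$model, "model.json")

fix <- makeLabeledDataset(8, "HWKDFY", 0.5, c(60, 150), seed = 99,
                          breakpointBacked = TRUE, dir = "fixture")
# drop the label column to get a plain N x 4 inference input
lab <- read.delim(fix$labeledFile, header = FALSE)
write.table(lab[, 1:4], "fusions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
runInference("fusions.tsv", "generic", fix$fasta, fix$gtf, "model.json",
             threshold = 0.8, output = "report.tsv")
#> 8 fusion row(s) reported, 4 at probability >= 0.80
readFusionReport("report.tsv")[, c("fusionPair", "oncProb")]
#>      fusionPair oncProb
#> 1 SYNL2A_SYNL2B       1
#> 2 SYNL1A_SYNL1B       1
#> 3 SYNL4A_SYNL4B       1
#> 4 SYNL3A_SYNL3B       1
#> 5 SYNL5A_SYNL5B       0
#> 6 SYNL8A_SYNL8B       0
#> 7 SYNL7A_SYNL7B       0
#> 8 SYNL6A_SYNL6B       0
```

The four motif-bearing fusions rank first at probability 1.00 and are the
only rows at or above the 0.8 threshold; their true labels are exactly
`1 1 1 1 0 0 0 0` in input order. The written `report.tsv` carries the full
14-column schema (`FusionPair`, `OncogenicProbability`, gene ids/names/
descriptions for both partners, `MainProteinLength`, `TruncatedProtein`,
`Gene5pComplete`, `Gene3pComplete`, `NumCandidates`, `MainProtein`).

Command-line wrappers over the same functions live in `inst/cli/`
(`inference.R`, `retrain.R`, `synthgen.R`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/inference.R", package="fusionDriveR"))')" \
  --input fusions.tsv --genome genome.fa --gtf annotation.gtf \
  --model model.json --threshold 0.8 --output report.tsv
```

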