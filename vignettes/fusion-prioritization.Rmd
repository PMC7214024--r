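---
title: "Prioritizing gene fusions from breakpoint pairs: methods and design"
author: "fusionDriveR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing gene fusions from breakpoint pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionDriveR)
```

## The problem

RNA-seq fusion callers emit long lists of candidate gene fusions, most of
which are passenger events. Deciding which candidates are plausible oncogenic
drivers is a ranking problem. fusionDriveR addresses it with a sequence-level
view: a fusion is characterized by the chimeric proteins it can encode, and a
learned classifier scores each protein's resemblance to proteins of known
oncogenic fusions. The inputs are deliberately minimal — a genome FASTA, an
Ensembl-dialect GTF, and per fusion only the chromosome and coordinate of the
5' and 3' breakpoints — so the tool slots in directly downstream of any
caller.

## From breakpoints to candidate proteins

For each fusion, the genes whose spans contain the two breakpoints are
resolved and, for every (5' gene, 3' gene) pair, one fused transcript is
attempted per pair of **coding** transcripts: all coding isoforms of both
genes are considered, because the breakpoint alone does not identify the
expressed isoform. The fused transcript is the 5' transcript's sequence from
its annotated start codon through the breakpoint-retained boundary, joined to
the 3' transcript's sequence from the breakpoint-retained boundary through
its transcript end.

Breakpoint semantics are the dominant caller convention: the 5' coordinate is
the **last** genomic base retained from the upstream gene and the 3'
coordinate the **first** base retained from the downstream gene, both read in
transcript orientation on minus-strand genes. Intronic breakpoints retain the
exons wholly on the kept side and contribute no novel sequence, because the
fusion transcript is a spliced product. Exonic breakpoints may cut mid-codon;
the junction codon then mixes bases from the two genes, which is exactly what
frameshift fusions look like. Two conservative rules handle degenerate
placements: a 5' breakpoint upstream of the start codon (nothing of the
upstream CDS retained, including a cut inside the start codon itself) and a
3' breakpoint past the first base of the downstream stop codon (nothing
coding gained) skip the transcript pair with a logged reason code rather than
inventing a rescue; there is no downstream-ATG rescue.

Translation starts at the 5' gene's annotated ATG and proceeds codon by codon
under the standard genetic code until the first stop. Three flags summarize
the outcome, mirroring the fields of the output report:

* **truncated** — the first stop encountered is not the downstream
  transcript's annotated stop (or no stop occurs at all);
* **5' gene complete** — the retained upstream portion includes the upstream
  gene's stop codon;
* **3' gene complete** — the retained downstream portion includes the
  downstream gene's start codon.

A junction is called in-frame when the first retained downstream CDS base
sits at its native codon phase in fused coordinates. This single phase
condition also covers the case where part of the downstream 5' UTR is
retained and translation reads through it into the CDS; splitting the test
into "junction at a codon boundary" plus a separate phase check misclassifies
that case, so the package uses the combined condition throughout.

Candidates within a gene pair are ordered by `(tx5, tx3)` identifiers and
deduplicated by amino-acid sequence, so isoform pairs that differ only
outside the retained regions do not inflate the candidate list.

## Scoring, aggregation and ranking

Each candidate protein is index-encoded over the 20 standard residues plus
`X` (index embedding rather than one-hot, as is standard in front of an
embedding layer), padded with zeros to `maxLen` (default 1500 residues,
tail-truncated beyond it) and scored by the classifier:

embedding (16) → 1-D convolution (64 filters, kernel 7, ReLU) → max-pooling
(width 4) → bidirectional LSTM (64 units per direction) → temporal max over
the recurrent outputs → dropout (0.3) → dense sigmoid.

The temporal max over LSTM outputs (rather than taking only the final hidden
states) lets evidence observed anywhere in a long protein reach the decision
head directly; for motif-like signals this materially shortens training
without changing the architecture family. All hyperparameters above are
package defaults surfaced in `modelConfig()` and `encoderConfig()`, every one
overridable.

The fusion's **oncogenic probability** is the *maximum* of its candidate
protein scores: a single high-scoring protein is enough to flag the fusion.
Results are ranked non-increasingly by probability (stable in input order on
ties, for reproducibility); a user threshold `thr` (default 0.8) defines the
"relevant" subset with a `>=` comparison, so a probability exactly at the
threshold is retained. Fusions for which no protein could be built carry `NA`
probability and a reason code; they sort after all scored rows and are
excluded from the thresholded view, since relevance is defined only for
scored fusions.

The forward/backward passes of the network are implemented directly in dense
matrix algebra (including backpropagation through time in both LSTM
directions) and are verified in the test suite against finite-difference
gradients, so the trainer depends on nothing beyond a BLAS.

## Retraining

Labels live on fusions (an N x 5 file adds a 0/1 oncogenicity column), but
the model consumes sequences, so every candidate protein inherits its
fusion's label — the only label-complete rule. Sequences observed under both
labels are dropped entirely (counted, never arbitrated). Classes are balanced
by seeded down-sampling of the majority class, which conserves the minority
class exactly and introduces no duplicated examples. Training minimizes
binary cross-entropy with Adam (learning rate 1e-3, batch 32, global gradient
norm clipped at 5) over a seeded, label-stratified 80/20 split, early-stops
on validation loss with patience 5, and restores the best weights.
Retraining starts from fresh weights by default; `warmStart` can seed the
weights from a previous archive. The archive is a single JSON file holding
the encoder configuration, hyperparameters and all weight tensors at full
precision — portable, diffable, and loadable by the inference mode, which
reproduces the trainer's validation scores to within floating-point
round-off.

## What the synthetic fixtures emulate

`makeGenome()` builds compact multi-gene genomes (contigs of a few kb):
genes with 5'/3' UTRs, multi-exon structure, introns, both strands, and
multiple isoforms generated by *in-frame cassette exons* — codon-aligned
blocks inside the CDS that can be skipped without moving the start or stop
codon or introducing an in-frame stop. Random CDS interiors are drawn from
the 61 sense codons, so reading frames are clean by construction.
`makeFusions()` samples breakpoints by class (exonic, intronic, 5' UTR,
after the 5' stop, before the 3' start, intergenic) and computes the
expected protein and flags for every transcript pair with an independent
oracle: plain string arithmetic over the generator's own truth tables and
seqinr translation, sharing no code with the builder.
`makeLabeledDataset()` plants a k-mer motif in the positive class (negatives
are rejection-sampled) and can realize each labeled sequence as a dedicated
single-exon gene pair plus breakpoint row, so the whole retraining path can
be exercised from files.

These fixtures emulate the *structure* of real annotation, not its
statistics: gene and intron lengths are uniform in narrow ranges, base
composition is uniform, there are no overlapping genes or non-coding
isoforms beyond what tests construct by hand, and the planted-motif signal
is far cleaner than the sequence determinants of real oncogenic fusions.
Passing tests therefore demonstrate that the mechanics — coordinate
arithmetic, splicing, strand handling, translation, flag semantics, learning
capacity, serialization — are correct, not that the default model
generalizes to real tumors; for real use the model should be retrained on
curated labeled fusions.

## Numerical and design choices

* Coordinates are 1-based inclusive end to end (the GTF convention);
  half-open arithmetic appears nowhere in the public surface.
* The stop codon is merged into the stored CDS when the GTF follows the
  Ensembl convention of excluding it, so spliced CDS extraction always ends
  at the terminal stop and completeness flags are well defined. Start/stop
  annotation flags fall back to inspecting the CDS termini when the explicit
  features are absent.
* Codons containing `N` translate to `X`; `X` has its own encoder index.
* The "main protein" reported for a fusion is the candidate achieving the
  maximum score, ties broken by greater length and then by transcript-id
  order — a deterministic choice consistent with max-aggregation.
* Report probabilities are printed with two decimals; flags as Yes/No; the
  14-column header is fixed and machine-parseable (`readFusionReport()`).
* Training at the scales used in the tests and the acceptance script
  (600 sequences, 200-residue window, at most 20 epochs) runs in about a
  minute per model on one CPU core; these sizes were chosen so the planted
  motif is comfortably learnable while the full verification loop stays
  interactive.
* Determinism: one integer seed controls fixture generation, initial
  weights, shuffling, dropout and balancing; identical seeds give identical
  datasets, weights and reports (floating-point scheduling aside).

## Known limitations

Only the canonical genetic code is supported (no selenocysteine
readthrough); read-through fusions of adjacent genes and breakpoint
refinement from read evidence are out of scope; GFF3 is not parsed;
chromosome-name aliasing beyond exact contig matching is the user's
responsibility. One caller adapter (star-fusion-style columns) ships behind
the format registry; other callers are a `registerCallerFormat()` call away.
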