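---
title: "Methods: ubiquitination-site prediction with resubinet"
author: "resubinet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ubiquitination-site prediction with resubinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resubinet)
```

## The prediction problem

Ubiquitination attaches ubiquitin to specific lysine (K) residues and is a
central regulatory post-translational modification. Given a protein
sequence and a candidate lysine, the task is binary classification: is the
lysine a ubiquitination site? `resubinet` implements the ResUbiNet
architecture for this task: each candidate is represented by a
fixed-length peptide window centred on the lysine, encoded into three
complementary feature channels, and scored by a hybrid neural network.

## Windows and datasets

A window of odd length $L$ (default 25) spans $(L-1)/2$ residues on each
side of the candidate lysine. Positions beyond a protein terminus are
padded with `-`; the pad symbol lies outside the amino-acid alphabet and
every encoder maps it to an all-zero feature row, so terminal windows
carry no spurious signal. Coordinates are 1-based in all files; the
centre of a window sits at 0-based index $(L-1)/2$ internally.

`buildDataset()` emits one positive window per annotated site and, for
each positive, one negative window centred on a non-annotated lysine
drawn without replacement from the same protein (seeded). Drawing
negatives from the same protein controls for composition differences
between proteins. When a protein has fewer eligible negative lysines
than positives, we emit what exists and warn with the protein id rather
than silently unbalancing the set; annotations pointing at non-lysine
residues are rejected at load time.

## Feature encoding

Each window yields three channels:

1. **Physicochemical** ($L \times 31$): 31 amino-acid properties from
   the AAindex database, min-max normalized per property over the 20
   standard residues, so every column spans exactly $[0, 1]$. The
   published model uses a 31-property selection available only as
   supplementary material; the packaged table
   (`inst/extdata/aaindex31.tsv`) is this package's curated selection of
   31 genuine AAindex accessions spanning the same classes —
   hydrophobicity, charge/electronic, steric and structure propensity —
   with accessions and descriptions documented alongside. All shape and
   normalization contracts are unaffected by the identity of the
   properties.
2. **Evolutionary** ($L \times 20$): each residue's row of the BLOSUM62
   substitution matrix (taken from `Biostrings`), min-max normalized over
   the whole matrix so the global minimum $-4$ maps to 0 and the maximum
   $11$ to 1. Whole-matrix scope preserves the relative ordering of all
   substitution scores; per-column scope would not.
3. **Contextual** (1024-vector): a protein-language-model embedding per
   window. Providers are pluggable: a `table` provider reads precomputed
   vectors (e.g. real ProtT5 output) keyed by `protein:position`; a
   `protrans` adapter wraps any per-residue embedding function and
   mean-pools it across the non-pad window residues (centre-residue-only
   pooling is a switch — the pooling convention is not fixed by the
   published description, and mean pooling is the dominant practice);
   and a `synthetic` provider generates label-correlated Gaussian
   vectors for offline work.

Normalization statistics come from the lookup tables alone, never from
data, so there is no train/test leakage through encoding, and encoding
is a pure function of the window string.

## Network architecture

The network has three inputs. The AAindex and BLOSUM62 channels each
pass through:

- a **transformer block**: multi-head self-attention (4 heads, key
  dimension 16) with an additive residual connection, layer
  normalization, a two-layer position-wise dense block (width 64) with a
  second residual connection, and a final layer normalization. The
  normalization order (attention, add, normalize) follows the published
  block diagram. The block preserves the $(L, d)$ sequence shape.
- a **residual convolution block**: a multi-kernel convolution (kernel
  sizes 3/5/7, 16 filters each, channel-concatenated), max-pooling
  (window 2), two standard convolutions (48 filters, kernel 3), and a
  squeeze-and-excitation (SE) block (ratio 8) that rescales channels by
  a sigmoid gate computed from globally average-pooled channel
  statistics. A kernel-size-1 convolution plus max-pooling projects the
  block input onto the main path's shape for the additive shortcut. All
  convolutions use length-preserving ("same") padding so the residual
  addition is well defined; the publication does not state the padding
  convention.

The two flattened sequence branches are concatenated and processed by
two dense layers (132, 48) with dropout (rate 0.3); the embedding passes
through two dense layers (160, 32); the fused vector passes through two
further dense layers (64, 32) and a sigmoid output neuron.

**Reconstructing the layer widths.** The exact widths of the published
model live in supplementary tables that this implementation does not
bundle. The published quantitative anchor is the trainable parameter
count, 399,411. The defaults above were fixed by setting every
convention-bound quantity to its standard value (heads, kernel sizes, SE
ratio, pooling) and solving the remaining dense widths so that the
parameter count matches exactly; within the searched neighbourhood of
conventional widths the solution is unique. Every dimension remains
overridable through `modelConfig()`, and `smallModelConfig()` provides a
narrow variant of the same topology for fast experiments.

## Training engine

No deep-learning framework is involved: the package implements forward
and backward passes for every layer (dense, layer normalization,
multi-head attention, 1-D convolution, max-pooling,
squeeze-and-excitation, dropout) in base R matrix code, together with
the Adam optimizer. Gradient correctness is established by
finite-difference checks through the entire network in the test suite
(relative error below $10^{-4}$ on sampled parameters).

Optimization follows the published recipe: Adam at learning rate
0.0005, binary cross-entropy, batch size 128. The epoch budget and
early stopping are not specified in the source description; the package
defaults to best-validation-loss checkpointing with patience 10 within a
bounded epoch budget. Probabilities are clipped at $10^{-7}$ inside the
loss for numerical stability; dropout is active only during training, so
inference is deterministic. Each fold's weights are independently
initialized (Glorot uniform) from the fold's seed.

`trainEnsemble()` performs stratified, seeded k-fold cross-validation
(default $k = 5$): each sub-model trains on $k-1$ folds with the held-out
fold as its validation set, and the ensemble prediction is the exact
arithmetic mean of the sub-model probabilities. `lengthSweep()` repeats
dataset construction, encoding and ensemble training over a grid of
window lengths — by default the 32 odd lengths 7 to 69 — and reports
per-split metrics per length.

## Evaluation

`evaluateScores()` reports accuracy, sensitivity, specificity,
precision, F1 and Matthews correlation coefficient at a decision
threshold (default 0.5 — the published results do not state one, so it
is exposed as a parameter), plus ROC AUC computed as the tie-corrected
Mann-Whitney rank statistic and precision-recall AUC by trapezoidal
interpolation over the distinct-score cut-offs. Metrics with a zero
denominator are reported as `NA` rather than silently as zero, so
degenerate sweep rows are visible. The test suite pins these
implementations against naive loop oracles, an $O(n^2)$ pairwise AUC
oracle and `pROC`.

## Sequence-pattern analyses

Three analyses compare positive and negative windows:

- `aaFrequencies()`: pooled residue frequencies per class, excluding the
  centre lysine by convention and all pad positions.
- `twoSampleLogo()`: for every position and residue, a two-sided Welch
  t-test on per-window occurrence indicators between classes; residues
  with $p < 0.05$ are reported as enriched or depleted. The Welch form
  is this package's choice (the source states only "t-test"), and no
  multiple-testing correction is applied by default to match the
  conventional two-sample-logo screen; Bonferroni and
  Benjamini-Hochberg switches exist. Under label permutation the flagged
  fraction calibrates to roughly the significance level.
- `vhseProfile()`: per-position class means of a VHSE descriptor
  component. The packaged VHSE table is transcribed from the published
  descriptor set (Mei et al. 2005, Biopolymers); VHSE1 tracks
  hydrophobicity, VHSE3 steric bulk and VHSE5 electronic properties.

## The synthetic benchmark

Real benchmarks for this task require an external site database and
multi-gigabyte language-model downloads, so the package ships a
generator that reproduces the *statistical structure* reported for real
data and makes the whole pipeline testable offline:

- positive-site flanks (positions $-4..+4$) enriched for the hydrophobic
  residues L/F/Y with probability $0.7 \cdot \text{motifStrength}$ per
  position;
- negative-lysine flanks ($-7..+7$) enriched for K/R/C/E with
  probability $0.6 \cdot \text{motifStrength}$;
- a uniform 19-letter background (no background lysines, so every K is a
  deliberate candidate and the centre contrast stays crisp);
- embeddings drawn as class mean plus unit Gaussian noise, the means
  separated by `signal` along a direction fixed by a separate
  `directionSeed` — the direction plays the role of the frozen embedding
  model, so independently simulated training and test sets share their
  class geometry, exactly as real language-model embeddings would.

At `motifStrength = 0` the two flank classes are statistically
indistinguishable and at `signal = 0` the embeddings carry no label
information; both null cases are tested. The generator does **not**
emulate protein-level redundancy, realistic amino-acid background
frequencies, motif position uncertainty, or the long-tailed difficulty
of real sites — so passing the learnability check demonstrates that the
architecture, encoders and training engine work end-to-end, not that
real-data performance matches published numbers.

## Problem sizes and reproducibility

The packaged experiments use 1000 proteins with two positive and two
negative lysines each (4000 balanced windows, $L = 25$), signal-3
embeddings, and the narrow `smallModelConfig()` for ensemble training
(5 folds, 5 epochs, patience 3); these sizes keep a full run in the
minutes range on a single CPU while leaving wide margins on the
learnability criterion (held-out AUC above 0.99 against the 0.90 bar).
All randomness — simulation, negative sampling, fold assignment, weight
initialization, batch shuffling, dropout — flows from explicit integer
seeds; training reproducibility is asserted to a loss tolerance of
$10^{-3}$ to allow for BLAS-level reordering.

## Known limitations

- The 31-property selection and the layer widths are reconstructions
  constrained by the published shapes and parameter count, not verbatim
  transcriptions of unavailable supplementary tables.
- The pure-R training engine is fit for the packaged problem sizes;
  training on a full-scale benchmark (tens of thousands of windows,
  hundreds of epochs) would want a compiled backend.
- The `protrans` adapter defines the bridge to a real language model but
  is exercised only by an interface-conformance mock; computing real
  ProtT5 embeddings requires external infrastructure.
- Negative sampling assumes non-annotated lysines are true negatives,
  which understates label noise present in real data.
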