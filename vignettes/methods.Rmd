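---
title: "Predicting linear B-cell epitopes with a two-branch sequence network"
author: "linearBCE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting linear B-cell epitopes with a two-branch sequence network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linearBCE)
```

## The problem

Linear B-cell epitopes (BCEs) are short contiguous stretches of an antigen
-- typically 11 to 25 residues -- that antibodies recognise.  Experimental
epitope mapping is slow and expensive, so sequence-based classifiers that
score a candidate peptide's probability of being an epitope are widely
used to prioritise candidates for vaccine and antibody work.  This package
implements such a classifier as a two-branch neural network, together with
the full evaluation protocol around it: stratified holdout and 10-fold
cross-validation, a kernel-width grid search, five branch-ablation
variants, activation export with t-SNE, and a synthetic benchmark
generator so every stage is testable without external data.

## The model

A peptide is uppercased, validated against the 20-letter amino-acid
alphabet `ACDEFGHIKLMNPQRSTVWY`, and quantised to an integer sequence with
the fixed code table X=0 (padding), A=1, C=2, ..., Y=20.  Sequences
shorter than the standardized length $L = 25$ are padded at the tail with
the code 0; longer sequences are tail-truncated with a warning (the
curated benchmarks this length was chosen for contain nothing longer than
25, so truncation only matters for arbitrary user input).  The integer
batch is embedded into $\mathbb{R}^{d}$ per position and fed to two
parallel branches:

* **Recurrent branch.** A bidirectional LSTM reads the $L$ positions in
  both directions; the per-position hidden states
  $h_t \in \mathbb{R}^{2u}$ (with $u$ units per direction) are pooled by
  feed-forward attention
  $$\alpha_t = \frac{\exp e_t}{\sum_{k=1}^{T} \exp e_k},
    \qquad c = \sum_{t=1}^{T} \alpha_t h_t,$$
  where the score $e_t = a(h_t)$ comes from a learnable scorer.  We use
  the affine-to-scalar form $e_t = \tanh(w^\top h_t + b)$.  The weights
  $\alpha_t$ are non-negative and sum to one, so the context $c$ is a
  convex combination of the hidden states.

* **Convolutional branch.** One 1-D convolution per active kernel width
  (defaults 11, 13 and 15), stride 1, 'same' zero padding so every scale
  sees all $L$ positions, ReLU activation, and global max pooling per
  filter.  Smaller kernels respond to local composition, larger ones to
  near-global patterns; using several widths at once is what "multi-scale"
  refers to.

The flattened branch outputs are concatenated, passed through dropout and
three dense layers of 64, 9 and 1 units; the final sigmoid unit is the
epitope probability.  Decision threshold 0.5, with ties classified
positive -- a fixed deterministic rule.

### Hyperparameters and defaults

The published description of this architecture fixes the code table, the
input length, the kernel widths and the 64/9/1 dense head but is silent on
everything else.  The remaining values are this package's fixed choices,
all carried in `modelConfig()` so they can be overridden:

| parameter | default | notes |
|---|---|---|
| `embedDim` | 64 | embedding width |
| `lstmUnits` | 64 | per direction; hidden states are 128 wide |
| `cnnFilters` | 64 | per scale |
| `dropoutRate` | 0.3 | applied once, after branch concatenation |
| `learningRate` | 1e-3 | Adam, $\beta_1 = 0.9$, $\beta_2 = 0.999$ |
| `batchSize` | 32 | shuffled each epoch |
| `epochs` | 50 | with early stopping (patience 10, min improvement 1e-4) when a validation set is supplied |

Padding code 0 is embedded like any other token; no masking is applied.
Padding to the maximum length (rather than the mean or minimum) is the
configuration the length experiment in the source protocol found best, and
the convolutions' zero 'same' padding keeps every kernel width up to $L$
valid.

### Ablations

`ablateConfig()` derives the five single-edit variants studied for this
architecture: removing the Bi-LSTM (its attention goes with it), the
smallest kernel scale, the two smallest scales, the entire CNN branch, or
the attention pooling.  "Scale 1" is read as the smallest kernel width,
matching the ascending ordering used throughout.  When attention is
removed the Bi-LSTM branch must still produce a fixed-width summary; we
use the concatenated final forward and final backward hidden states, the
conventional fallback.  Removing both branches at once is refused.  Every
variant has strictly fewer trainable parameters than the full model, which
the tests assert.

## Training and evaluation protocol

Training minimises mean binary cross-entropy with Adam.  All randomness
(initialization, epoch shuffles, dropout masks) is derived from
`config@seed`, so runs are bit-reproducible.  Metrics follow the standard
confusion-table definitions: sensitivity $Sn = TP/(TP+FN)$, specificity
$Sp = TN/(TN+FP)$, accuracy $ACC = (TP+TN)/n$, and the Matthews
correlation coefficient
$$MCC = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FN)(TN+FN)(TP+FP)(TN+FP)}}.$$
A metric whose denominator is zero (a fold with no negatives, say) is
reported as 0 and flagged rather than raising, which keeps fold
aggregation total; the definitions are simply undefined there.  A useful
identity the tests exploit: the MCC of a binary confusion table equals the
Pearson correlation of the 0/1 truth and prediction vectors, which gives
an independent oracle for the formula implementation.

Splits are stratified by label throughout.  The balanced benchmark
composition makes stratification the natural reading of folds "of
equivalent or approximately equivalent size"; whether the original
protocol stratified is unknowable from its description, so this is
recorded as a default, not a fact.  `stratifiedFolds()` deals each
shuffled class round-robin, so fold sizes differ by at most one per class;
per-class train counts in `holdoutEval()` apportion the overall target by
largest remainder so the split sizes come out exact.  Cross-validation
trains one fresh model per fold (fold $f$ reseeds at `seed + f`); no
weights are reused.  `scaleSearch()` evaluates every unordered triple of
distinct candidate widths (ten triples for candidates 7, 9, 11, 13, 15)
by stratified holdout and ranks by ACC, then MCC, then smaller kernels --
the joint ACC/MCC ordering mirroring how the best scale combination was
originally selected.

## The synthetic benchmark generator

`generatePeptides()` emulates the *shape* of the curated epitope sets this
model targets: balanced classes, lengths uniform on 11--25 (so minimum 11,
maximum 25; the uniform mean of 18 is close to, though not exactly, the
benchmark mean of 16), uniform background residue usage, and a planted
5-mer motif as the class signal.  The motif overwrites a window at a
uniformly chosen offset -- overwriting rather than inserting keeps the
length distribution exact -- in exactly `round(penetrance * nPos)`
positives and `round(contamination * nNeg)` negatives (round half up, with
carriers chosen by assignment rather than per-record coin flips, so the
counts are exact for every seed; non-carriers are resampled until they do
not contain the motif by chance).  Penetrance and contamination form a
difficulty dial: at penetrance 1 / contamination 0 the task is fully
separable and a trained model should approach perfect test metrics; at
penetrance 0 the classes are exchangeable and MCC should sit near zero.

The shipped learnability check pairs a real training run with a
label-shuffled control.  The control uses `shuffleLabels()`, a *balanced*
permutation in which each original class contributes a proportional share
of the positive labels, so the permuted labels are exactly independent of
the true classes.  A plain random permutation is not an exact null here:
it leaves a small chance association between the motif and the permuted
labels (about $\pm 2\%$ at $n = 800$), training to convergence amplifies
whatever direction that association has, and the fully separable test set
then rewards it -- we observed control test accuracies as high as 0.7 this
way.  Conditioning the permutation on exact balance is the standard
permutation-test remedy and restores chance-level control accuracy.

What passing on this generator does *not* show: real epitopes are not
defined by a single fully penetrant motif, their residue composition is
far from uniform, and negatives drawn from the same antigens share
composition with positives.  The generator validates the machinery --
encoding, optimisation, protocol bookkeeping -- not biological accuracy.
Reproducing published benchmark numbers requires the external benchmark
files (see `scripts/reproduce_benchmark.R` in the source repository).

## Numerical choices

* Softmax scores are max-shifted before exponentiation; attention weights
  sum to 1 within 1e-6 by construction.
* Sigmoid outputs are clamped at 1e-12 inside the loss only; probabilities
  are reported unclamped.
* Glorot-uniform initialization everywhere except the embedding
  (uniform on $\pm 0.05$); LSTM forget-gate biases start at 1.
* Global max pooling breaks ties by first position; `scaleSearch()` breaks
  ranking ties by MCC and then by smaller kernels; threshold ties classify
  positive.
* Training stops with an error on a non-finite loss instead of returning a
  diverged model.
* Backpropagation through the whole network is verified against central
  finite differences in the test suite.
* t-SNE (used for activation visualisation) is the exact
  $O(n^2)$ algorithm with perplexity calibration by binary search, early
  exaggeration and momentum descent -- adequate for the few hundred points
  plotted here, deterministic given its seed.

## Problem sizes used in the shipped checks

The package's own checks run entirely on generated data at sizes a single
CPU handles comfortably: the learnability check trains the default model
on 800 peptides (640 train / 160 validation after the internal split) and
tests on 200; the cross-validation and ablation checks use 200 peptides;
the kernel-width grid uses 160 peptides at 5 epochs per combination.
These sizes are the package's choices for its reference checks; all are
parameters the user can raise.

## A worked example

```{r example, eval = FALSE}
recs <- generatePeptides(synthSpec(nPos = 400, nNeg = 400, seed = 101))
cfg  <- modelConfig(seed = 7)
fit  <- trainModel(cfg, encodeBatch(recs, cfg@L))
test <- generatePeptides(synthSpec(nPos = 100, nNeg = 100, seed = 202))
evaluateModel(fit, encodeBatch(test, cfg@L))
```

## Known limitations

* Pure-R training: a minibatch of 32 length-25 peptides takes on the
  order of a tenth of a second, entirely adequate for the benchmark sizes
  this method targets (hundreds to thousands of peptides) but not for
  proteome-scale training.
* Only linear epitopes: no conformational-epitope support, no structural
  or evolutionary features, no pretrained protein language-model
  embeddings.
* Sequences longer than `L` are truncated, a policy choice the original
  method never needed to make.
* The early-stopping rule is active only when a validation batch is
  supplied; unsupervised stopping (e.g. on training loss) is deliberately
  not implemented.
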