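---
title: "Chromosome-aware training and evaluation of hybrid m6A site predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-aware training and evaluation of hybrid m6A site predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6aloco)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal modification of
eukaryotic mRNA. Sequence-based predictors classify fixed-length windows
centered on an adenosine as methylated or not. Most published predictors are
evaluated with a *random split* (RS) of windows into training and test sets.
Because windows from the same chromosome — with its region-specific base
composition and local sequence biases — end up on both sides of an RS split,
the model can exploit those shared regional features, and the resulting test
metrics overstate how well the predictor generalizes to unseen genomic
context. *Leave-one-chromosome-out* (LOCO) evaluation removes this leakage
channel completely: each fold holds out every window of one chromosome and
trains on the rest.

`m6aloco` implements the full pipeline around this comparison: encodings,
a convolutional model family, balanced-replicate construction, RS and LOCO
split plans with a leakage auditor, the metric suite, and a synthetic data
generator whose *chromosome-composition confounder* lets you reproduce the
RS-inflation phenomenon on your laptop, with no external data.

## Data model

A dataset is a tibble of records `(id, chromosome, sequence, label)` with a
common window length `L` (default 2001). On ingest, sequences are
uppercased, `U` is mapped to `T` (one canonical DNA alphabet downstream,
even for mRNA data), and any other ambiguity code is mapped to `N` with a
warning rather than an error, because real genome windows contain ambiguity
codes. Windows of the wrong length are rejected by default — fixed `L` is an
architecture contract — unless a padding policy (`center_crop`, `n_pad`) is
chosen explicitly. Any genomic coordinates in label sidecars are treated as
opaque metadata: only the chromosome label is ever used, because chromosome
identity is the unit of the LOCO protocol. Chromosome labels themselves are
opaque strings; the package never assumes, say, that `chr23` means chrX.

## Encodings

Two representations feed the models:

* **k-mer composition** (`encode_kmer()`): counts of every length-`k`
  subsequence under a step-1 sliding window, a `4^k`-dimensional vector
  (1024 for the default `k = 5`). The index order is lexicographic over
  (A, C, G, T) — a choice the package fixes so columns are comparable
  across runs. "Frequency" is the raw occurrence count by default (a
  10-nt window has `10 - 5 + 1 = 6` counted 5-mers); `normalized = TRUE`
  divides by the number of valid windows for scale invariance. Windows
  containing `N` contribute to no entry, so ambiguity never fabricates
  signal.
* **one-hot** (`encode_onehot()`): `A = (1,0,0,0)`, `C = (0,1,0,0)`,
  `G = (0,0,1,0)`, `T = (0,0,0,1)`, `N` = all zeros. The matrix is stored
  positions-by-channels (`L x 4`) because the convolution engine consumes
  (length, channels); descriptions of the same encoding as a `4 x L`
  matrix are just the transpose, with no information change.

## The model family

Three binary classifiers share one convolutional trunk over the one-hot
window and differ in how handcrafted k-mer features join the decision
layer:

| variant | decision-layer input |
|---|---|
| SM (simple) | flattened CNN features |
| HM (hybrid) | CNN features ++ raw `4^k` k-mer counts |
| DHM (deep hybrid) | CNN features ++ `dense(64, ReLU)` transform of the k-mer counts |

The trunk at full scale is `Conv1D(64, kernel 23, stride 1, same padding) ->
ReLU -> MaxPool(15) -> Dropout(0.5) -> Conv1D(128, kernel 33) -> ReLU ->
MaxPool(15) -> Dropout(0.5) -> Flatten`, followed by a final dropout, one
batch-normalization layer, and a sigmoid dense unit. At `L = 2001` the
length chain is `2001 -> 133 -> 8`, the flatten width `8 * 128 = 1024`, and
the decision-layer widths are 1024 (SM), 2048 (HM), and 1088 (DHM). Two
geometric facts are forced by that chain and adopted as defaults:
convolutions must use length-preserving ("same") padding, and pooling must
be non-overlapping (stride = pool size) with floor truncation.

Training minimizes binary cross-entropy with Adam (learning rate 0.001),
batch size 64, 70 epochs — the standard regimen for this family. There is
no early stopping and no learning-rate schedule. All randomness (weight
initialization, shuffling, dropout) derives from one integer seed, so runs
are bit-reproducible.

The whole engine — im2col convolution, pooling, inverted dropout, batch
normalization, Adam — is implemented in R on top of BLAS matrix products
and verified by finite-difference gradient checks during development;
training at desk scale takes seconds per model.

Two design points were genuinely open and resolved as follows:

* **Kernel sizes.** Narrative descriptions of this architecture family
  circulate with kernels 13/23 while the layer table that fixes the shape
  chain uses 23/33. The package defaults to 23/33 — the table is the
  reproducible artifact — and both are constructor arguments.
* **Batch-norm placement.** The layer table omits batch normalization while
  the prose mentions it once, after dropout. The package places a single
  batch-norm on the decision-layer input (after the final dropout, before
  the sigmoid dense), which honors the prose without changing any printed
  shape; `batch_norm = FALSE` disables it.

### Desk-scale profile

Tests and examples use a documented reduced profile,
`model_spec_fast()` + `train_config_fast()`: `L = 201`, conv layers 16/9 and
32/5, pools of 5 (chain `201 -> 40 -> 8`, flatten 256), trunk dropout 0.1,
a 3-mer branch (64 dimensions), trained 10 epochs with Adam at 0.01 and
batch 16. Two of these reductions matter beyond speed. First, at a few
hundred training windows the full-scale dropout of 0.5 leaves the small
nets underfit within a 10-epoch budget, so the profile lowers it. Second, a
1024-dimensional k-mer branch against a few hundred training examples
memorizes the training set outright (training loss collapses while held-out
discrimination stays at chance), so the profile shrinks the branch to
`k = 3`, keeping handcrafted-feature capacity proportionate to everything
else. The faithful full-scale defaults are untouched.

## Splitting machinery

`balance_negatives()` implements the standard treatment of the roughly 1:5
positive:negative imbalance of m6A benchmarks: shuffle the negatives once
(seeded), deal them round-robin into `n_subsets` disjoint subsets — sizes
differ by at most one, and no record is discarded even when the negative
count is not divisible (54,949 negatives into five subsets gives four of
10,990 and one of 10,989) — and pair each subset with the full positive set.

`random_split()` builds the RS plan: an independent test set of
`round(0.2 n)` records plus 5 cross-validation folds partitioning the
training pool. Stratification by label is on by default; balanced folds
stabilize small-fold metrics. `loco_split()` builds one fold per
chromosome, ordered by natural sort (`chr2` before `chr10`), each testing
exactly the held-out chromosome. A chromosome whose records are all one
class is allowed with a warning: its class-conditional metrics will be
undefined and are excluded from averages with the count disclosed, rather
than imputed as zero, which would bias summaries.

`audit_split()` re-derives every invariant from the id lists (disjointness,
partition, zero train/test chromosome overlap) and throws on any violation;
the test suite includes negative controls where deliberately corrupted
plans must make the auditor fail. Plans serialize to JSON for exact reruns.

## Metrics

Threshold metrics use the conventional cut of 0.5 with ties called
positive (documented, since the convention is arbitrary). Accuracy,
sensitivity, specificity and MCC follow the standard confusion-matrix
formulas; any zero denominator yields an explicit undefined value with a
reason, never a silent 0. AUC-ROC is computed as the tie-corrected
Mann-Whitney rank statistic, which equals the trapezoidal ROC integral on
finite samples and is exact under ties. Confidence intervals default to the
normal approximation `mean ± z * sd / sqrt(n)` with `z = 1.959964` at 95%
and the sample (n-1) standard deviation — the denominator convention is the
package's own and stated here — with a seeded percentile bootstrap as an
alternative. LOCO summaries are the unweighted mean over the 23 (or
however many) per-chromosome reports.

Every metric is cross-checked in the test suite against independent
brute-force implementations (exhaustive pair counting for AUC, direct
formula evaluation for the rest) on hundreds of random inputs, plus the
label-swap and monotone-transform invariance laws.

## The synthetic generator and what it does (not) show

`generate_dataset()` emulates the geometry of the published human m6A
benchmark: windows of length `L` centered on an adenosine, chromosome
labels, roughly 1:5 imbalance at default sizes, positives carrying one
instance of the degenerate DRACH consensus (`[AGT][AG]AC[ACT]`, the motif
class in which most m6A sites occur) with its methylated A at the window
center, negatives carrying one at a low rate. Motif instances are sampled
uniformly over the letters each degenerate position allows, mimicking
biological motif variability. Each chromosome has its own background base
composition: offsets evenly spaced across chromosomes scale with the
confounder strength `confound` in `[0, 1]`, spanning GC 0.35-0.65 at full
strength. The confounder acts only through the background, never through
the motif, so the "cheating" feature is cleanly separable from the true
signal and the RS-vs-LOCO gap is attributable.

`make_confounded_pair()` additionally couples label to chromosome
(positives preferentially on high-GC chromosomes, factor
`1 ± 0.8 * confound * offset`), which is what makes composition a usable
shortcut under RS but not under LOCO: within a held-out chromosome the
composition is constant across classes, so it carries no discriminative
signal there. Its default configuration — 250 + 250 windows of length 201
over six chromosomes, motif insertion 0.6 vs 0.2, `confound = 0.8` — was
fixed once as the package's study condition: the motif signal is
deliberately modest so that the compositional shortcut is worth exploiting
and the inflation is visible rather than compressed against the AUC
ceiling. With `confound = 0` the same construction is the matched
unconfounded control. At this scale and training budget the desk-scale SM
does not recover the weak motif signal, so the LOCO estimate sits near
chance while the RS estimate is lifted purely by leakage — the cleanest
possible illustration that an RS number can be all shortcut.

What the generator does *not* model: transcript structure, tissue
specificity, homology between windows, positional autocorrelation of real
m6A-Atlas sites, or any composition-label coupling subtler than a
monotone GC gradient. Passing the synthetic gap experiment therefore shows
that the *machinery* (splits, training, evaluation) detects leakage when it
exists; it does not quantify how much leakage a real benchmark contains.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely at desk scale, the
package's chosen trade-off between statistical resolution and turnaround:
the learning-sanity experiment uses 1,000 windows of length 201 with three
seeds per variant; the leakage-gap experiment uses 500 windows over six
chromosomes, three seeds, under both the confounded and control settings;
metric oracles use 500 random small inputs. Full-scale runs
(`synth_config_benchmark()`, `model_spec()` defaults, 70 epochs) use the
same code paths and are minutes-to-hours of CPU; nothing in the package
requires a GPU. Numerical details worth knowing: batch-norm uses eps 1e-3
and momentum 0.9 on running statistics; predicted probabilities are clipped
at 1e-7 inside the loss only; Glorot-uniform initialization throughout; the
t-SNE view is an exact (dense) implementation suitable for up to a few
thousand points, with seeded gradient descent and early exaggeration.

## Limitations

* The training engine is single-threaded R; it is meant for desk-scale
  experimentation and faithful full-scale reproduction when given time,
  not for high-throughput screening.
* One-hot arrays are held in memory (`B x L x 4` doubles); at the full
  benchmark scale encode per balanced replicate rather than the whole
  negative set at once.
* LOCO eliminates chromosome-level leakage only; homology-aware or
  position-overlap-aware splitting is out of scope.
* The confidence intervals describe variation across folds, chromosomes,
  or replicates of *this* pipeline — each table states its dispersion
  source — and are not comparable across papers that leave the source
  unstated.
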