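---
title: "Deep-layer descriptors and SVM ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-layer descriptors and SVM ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerfuse)
```

## The problem and the model

Biological image collections (fluorescence microscopy of organelles, tissue
histology, virus TEM) are usually small — hundreds to a few thousand images —
which makes end-to-end training of a deep network prone to overfitting. A
robust alternative is transfer learning by *feature extraction*: run each
image through a frozen (or lightly fine-tuned) convolutional backbone, read
activations off several layers, and train a conventional classifier per
layer. Final layers encode semantics; inner layers encode texture, which is
often exactly what distinguishes organelle stains or virus morphologies.

The obstacle is dimensionality. An inner layer emits an activation tensor
$A \in \mathbb{R}^{M \times N \times D}$ whose flattened size easily exceeds
$10^5$, far too wide for an SVM on a few hundred samples. `layerfuse`
implements a family of *reduction operators* mapping each tensor to a
fixed-length descriptor, trains one RBF-SVM per (layer, operator) pair, and
fuses the per-unit class scores by a normalized sum rule.

### Layer selection

Layers are enumerated as named activation-producing nodes in forward order.
From $L$ enumerated layers the SVM-feeding subset is: the middle layer
$\lceil L/2 \rceil$, then one layer after every 10 toward the output, plus
the last four layers always. Reduction only applies to layers emitting
strictly more than $T = 5000$ features; smaller layers (typically the last
four) feed the SVM raw.

The enumeration granularity in modern graph networks is genuinely ambiguous;
we enumerate every conv / relu / pool / fc node of the sequential fixture
backbone, which makes the "every 10" walk well defined, and document the
resulting list per architecture via `enumerate_layers()`. The middle index is
$\lceil L/2 \rceil$ and the walk steps $+10$ in enumeration indices — the
simplest consistent reading of the rule.

### Reduction operators

With budget $B = 1000$ and channel count $D$:

* **DCT (local)** — each channel's $M \times N$ map is transformed by the
  orthonormal 2-D type-II DCT and the $\max(1, \lfloor B/D \rfloor)$
  lowest-frequency coefficients are kept in zig-zag order from the
  zero-frequency corner; channel blocks are concatenated. Low frequencies
  carry most of the energy, so truncation is a principled compression.
* **g-DCT (global)** — the whole tensor is flattened channel-major into one
  sequence, transformed by the 1-D orthonormal DCT, and the first $B$
  coefficients kept.
* **PCA** — per channel (local) or on the flattened layer (global), with the
  component budget clipped to the data rank (with a warning).
* **CHI** — features are discretized into 10 quantile bins computed on the
  training fold, a bin-by-class contingency table is formed per feature, and
  $X^2 = \sum_i (O_i - E_i)^2 / E_i$ ranks the features; the top $B$ are
  kept. The bin count is a design choice (the statistic is defined on
  categorical data; quantile binning makes it scale-invariant).
* **LBPCHI** — each channel is min–max normalized to $[0, 255]$, its 59-bin
  uniform local binary pattern histogram is extracted
  ($N = 8$ neighbors, radius $R = 1$; the 58 codes with fewer than three
  circular 0/1 transitions get a bin each, all others share one), histograms
  are concatenated over channels, and chi-square selection reduces to $B$.
* **CoOC** — co-occurrence pooling: activations strictly above the tensor
  mean are masked ($\rho_A$), and each position's masked neighborhood sum
  over all channels within a $(2r+1)^2$ window is accumulated, weighting the
  position's own channel by $\varepsilon$ (default $0$, radius $r = 1$) and
  every other channel by 1; the co-occurrence tensor is summarized by the
  per-channel spatial mean — one value per channel. The per-channel summary
  statistic is unspecified in the original formulation; the mean is the
  package's choice (sum differs only by a constant factor per layer shape).
* **GEP** — global entropy pooling: per channel, min–max normalize to
  $[0, 255]$, histogram into 255 equal-width bins (255 exactly, not 256),
  normalize to probabilities, and return $-\sum_j p_j \ln p_j$. Bounded by
  $\ln 255 \approx 5.5413$; a constant channel is defined to have entropy 0.
* **GMTP** — global mean-thresholding pooling: the threshold $T_g$ is the
  mean over all channels and positions, and each channel reports the
  fraction of its elements strictly below $T_g$.

Strictness conventions follow the definitions' wording ("greater than" for
$\rho_A$, "below" for GMTP), so a constant tensor yields all-zero CoOC and
GMTP outputs. GEP and GMTP are invariant to positive affine rescaling of the
tensor, and normalization statistics are per-image (per-training-set
statistics would leak fold information and are not used).

The per-channel budget $\lfloor B/D \rfloor$ is floored with a minimum of
one coefficient per channel, so descriptor length deviates from exactly 1000
when $D \nmid B$ and exceeds it when $D > B$; the alternative (dropping
channels) would discard whole feature maps.

### SVM units and fusion

Every unit is an RBF-SVM with the generic settings $C = 1000$,
$\gamma = 0.1$ — deliberately untuned, as the pipeline's claim is robustness
under fixed hyperparameters. Two package-level conventions make these
settings meaningful across heterogeneous descriptors:

* **Row L2 normalization.** Descriptor rows are normalized to unit length
  before fitting and scoring. Squared distances are then bounded by 4
  regardless of whether a layer emits 3 or 1000 features, so a fixed
  $\gamma$ behaves comparably across units.
* **Deterministic probability-like scores.** Sum-rule fusion needs
  commensurable scores. One-vs-one decision values $f_{ij}$ are mapped
  through a logistic link $r_{ij} = (1 + e^{-f_{ij}})^{-1}$, averaged per
  class over its $K - 1$ pairings, and row-normalized, giving per-class
  scores in $[0, 1]$ summing to 1. (The libsvm-style Platt calibration was
  rejected because its internal cross-validation is randomized, breaking
  exact reproducibility of fitted units.)

Fusion is the elementwise sum of unit score matrices divided by the number
of units; with several backbones each backbone's ensemble is normalized
before the cross-backbone sum. Named recipes (`"DCT"`, `"g-DCT"`,
`"DCT+GMTP"`, `"(DCT+PCA+GMTP)-2"`, `"TunLayer-3"`, `"TunFusLayer"`, ...)
are parsed by `parse_recipe()`; a `-2` recipe excludes the two deepest
selected layers from SVM feeding, and a two-method `-2` recipe accepts two
independently trained backbones, one per method, to increase diversity.

### Fine-tuning

`fine_tune()` minimizes softmax cross-entropy with momentum-0.9 SGD at the
canonical profile: batch size 30, learning rate 3e-4, 20 epochs, the final
fully connected layer at 20 times the base rate, and augmentation by random
reflections on both axes plus two independent per-axis rescale factors drawn
uniformly from $[1, 2]$ (implemented as a center zoom-in resample). The
optimizer beyond these settings is unstated in the protocol the defaults
come from; momentum SGD is the conventional choice. All desk-scale analyses
in the package use the untuned fixture backbone; fine-tuning is exercised on
small fixtures only.

### SFFS

`sffs_select()` implements sequential forward floating selection over a pool
of trained units: forward inclusion of the candidate maximizing fused
validation accuracy; after each inclusion a floating exclusion that drops
the member whose removal most helps, accepted only on strict improvement
over the best value recorded at the reduced size (strictness prevents
cycles; a hard iteration cap of $10\,|pool|$ guards termination); and a
final backtracking replacement pass that swaps members of the incumbent
subset for better-performing pool units until no single swap strictly
improves. The returned subset is the best subset of the target size
evaluated anywhere during the search. The stopping rule is a fixed target
size (matching usages like "SFFS(10)"), and the evaluation callback is
injectable so any validation protocol — held-out fold or
leave-one-dataset-out — can drive the search. Note that for target sizes
above 1 the optimal subset need not contain the best single unit, and a
fused pair can score below the best singleton; the search therefore reports
the best evaluated subset rather than assuming monotonicity.

## The synthetic study conditions

`gen_texture_dataset()` emulates the class structure of small biological
texture collections: each class is a sinusoidal grating with a distinct
orientation–frequency pair plus additive Gaussian noise. Defaults — 3
classes, 30 images per class, 64 × 64 pixels, amplitude 0.25 around
mid-gray, noise sd 0.1 — were fixed once as a desk-scale analogue of the
smaller real collections (a few hundred images, 5-fold cross-validation) and
are deliberately easy enough that a raw-pixel nearest-centroid classifier
exceeds 90 %: the point of the fixture is to verify pipeline mechanics
(shapes, budgets, fold hygiene, fusion), not to pose a hard recognition
problem. What passing tests on it do *not* show: robustness to staining
variation, scale changes, class imbalance, or any real microscopy
point-spread characteristics — none of which the generator imitates.

The fixture backbone (`tiny_backbone()`) is a seeded 3-block conv–pool stack
(channel widths 8/24/40, then 64-wide and class-wide fc stages, 12
enumerable nodes). Widths were chosen so the middle selected layer (`pool2`,
$16 \times 16 \times 24 = 6144$) exceeds the 5000-feature threshold — the
reduction path is genuinely exercised end to end — while the whole forward
pass stays in the tens of milliseconds. Its weights are random (seeded), not
pretrained: random convolutional projections preserve texture frequency
content, which suffices for the grating classes and keeps the package free
of binary checkpoint files.

## Numerical choices

* DCT via zero-padded FFT ($O(n \log n)$), orthonormal scaling; full-budget
  transforms invert to below $10^{-8}$.
* Zig-zag coefficient order: JPEG-style anti-diagonal sweep generalized to
  rectangles; any fixed low-frequency-first order would do, and this one is
  conventional.
* Histogram bins for GEP: exactly 255 equal-width bins on $[0, 255]$ (the
  published definition's count, kept verbatim).
* LBP bit weights follow the standard $2^n$ for neighbor index
  $n = 0 \ldots 7$ counterclockwise from east; $s(0) = 1$ (ties count as
  "greater or equal").
* Chi-square expected counts come from product marginals; cells with
  $E = 0$ are skipped; a constant feature scores 0.
* Argmax ties in prediction resolve toward the first class column;
  selection ties toward the lower column/unit index. All tie-breaks are
  deterministic.
* Stratified folds deal each class round-robin after a seeded shuffle, with
  a rotating starting fold, so per-fold class counts deviate from global
  proportions by at most one sample.

## Problem sizes used in the shipped analyses

The package's own evaluations (test suite and `scripts/acceptance.R`) run
the full pipeline on 90-image synthetic datasets under 5-fold
cross-validation, with medians over 5 dataset seeds for recipe comparisons;
operator–oracle checks use 20 seeded tensors per operator; SFFS is compared
against exhaustive search on 20 seeded pools of 4–6 units. These sizes were
chosen so a complete run takes a couple of minutes on a laptop while every
code path (reduction, RAW passthrough, fitting, fusion, selection) is
exercised.

## Known limitations

* Only sequential backbones are supported; the registry ships the seeded
  fixture family, not ImageNet-scale pretrained topologies, so absolute
  accuracies on real collections are out of scope here.
* Chi-square binning (10 quantile bins) and the CoOC per-channel summary
  (mean) are conventions where the underlying definitions are silent.
* The SVM score scale is a package convention (logistic-linked one-vs-one
  averaging); other monotone couplings would reorder close fusions.
* `fine_tune()` is a reference implementation in pure R: correct and
  reproducible, but not fast enough for large-scale training.
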