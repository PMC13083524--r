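---
title: "Dual-attention multimodal MIL: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention multimodal MIL: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A whole-slide image (WSI) is far too large to classify directly, and only a
slide-level label is available, so the slide is treated as a *bag* of
256-pixel patches under multiple-instance learning (MIL): patch features
are extracted, aggregated by attention into one slide vector, and
classified. `dualmil` implements a lightweight *end-to-end* variant of this
pipeline — the convolutional patch encoder is small enough to be trained
jointly with the aggregator and classifier — and fuses the image bag with a
second, molecular "bag": per-patient gene-set expression features derived
from RNA-seq. The intended tasks are two-class tumor classification
problems (e.g. glioma grade II vs III, LUAD vs LUSC, Luminal A vs TNBC),
where morphology and transcriptome are known to carry complementary
signal.

## Preprocessing

**Tiling and tissue filtering.** Slides are cut into a non-overlapping
grid of square patches (default 256 px; partial edge tiles are dropped so
every patch tensor has identical shape). A single Otsu threshold is
computed per slide on the grayscale histogram — per-patch thresholds would
be degenerate on uniform patches — and a patch's tissue fraction is the
proportion of pixels strictly darker than that threshold, since stained
tissue is darker than the glass background. Patches are *valid* when
tissue occupies strictly more than 90% of their area. Because tissue
content varies across patients, the per-patient patch budget is equalized
at the cohort minimum of valid-patch counts (optionally capped, e.g. at
64). Where a patient has more valid patches than the budget, the default
selection is deterministic — highest tissue fraction first, ties broken by
grid coordinates — with a seeded uniform-sampling policy available; the
selection rule is a package choice, made deterministic for
reproducibility.

**Gene-set features.** Upstream differential-expression and gene-set
enrichment analysis are *inputs* here (a GMT file plus per-set adjusted
p-values), not computations this package performs. Sets with adjusted
p < 0.01 are retained; GO-derived and KEGG-derived collections are used
independently, never merged. Counts are TPM-normalized using a per-gene
length table (TPM is undefined without lengths; the table's provenance is
the caller's responsibility, and synthetic cohorts generate one), then
log2-transformed with pseudocount 1 so zero counts stay at zero. Because
sets have different sizes, each patient's sets are zero-padded to the
maximum set size alongside a binary validity mask, and a single shared
autoencoder (padded width → 256 → D, tanh activations) compresses each set
row to the image feature dimension D. The loss is the masked MSE
`sum(mask * (x - xhat)^2) / sum(mask)`, and the padded entries are also
zeroed on the way *in*, so padding influences neither activations nor
gradients — exactly, not approximately. The latent layer is tanh-bounded:
unbounded latents (magnitudes in the tens) were observed to saturate the
downstream attention softmaxes, while `[-1, 1]` latents match the scale
the transformer expects. One autoencoder is shared across all sets —
that is what unifying shapes by padding enables — and it is trained before
and frozen during MIL training, like the enrichment step.

## The backbone and its reduction

The patch encoder is a small mobile-style network built from universal
inverted bottleneck (UIB) blocks: an optional 3x3 depthwise convolution,
a 1x1 expansion, an optional mid depthwise convolution (carrying the
stride), and a 1x1 projection. A block is *removable* exactly when it has
stride 1 and equal input/output widths, so deleting it cannot change any
downstream shape. Two reductions make the encoder light enough for joint
training:

1. **UIB elimination** — the ten removable blocks are deleted;
2. **APoZ pruning** — channels of the high-width final 1x1 convolution are
   ranked by their *average percentage of zeros* (fraction of
   post-ReLU activations equal to zero over a seeded calibration batch,
   default 256 patches) and only the lowest-APoZ channels are kept.
   Pruning takes a kept-channel budget rather than an APoZ threshold, so
   the resulting parameter count is exact and reproducible.

The reference configuration is pinned by its two printed parameter
budgets: 340,992 learnable scalars before reduction and 68,880 after
(a ~80% reduction). No published architecture at these sizes specifies
the truncation point, block flags or head width, so this package fixes a
concrete family — a 16-channel stem; three strided ExtraDW-style blocks
(16→32, 32→64, 64→64 with expanded widths 64, 83, 253); ten removable
width-64 blocks (seven IB-style with expanded widths 172 and 171, three
FFN-style with 121, 121, 120); and a 1x1 head of 1024 channels pruned to
256 — whose `count_params()` lands on both budgets exactly. Parameter
counting includes kernels, biases and two normalization affine terms per
channel. Desk-scale experiments use `tiny_backbone_spec()`, a smaller
member of the same family (64-px patches, D = 32).

Every convolution is followed by a learnable per-channel affine (the two
"normalization affine terms" per channel in the parameter counts) rather
than a statistic-based normalizer. The choice is deliberate: per-patch
(instance) statistics erase absolute intensity differences between
patches — precisely the kind of signal chromatin-spot density carries —
and batch statistics would make a patch's features depend on its bag
mates, breaking the per-patch purity of feature extraction (duplicating
or permuting patches must duplicate or permute feature rows — a tested
invariant). The network is shallow enough that plain Adam trains it
stably without normalizing statistics; training also applies decoupled
weight decay (default 1e-2 on weight matrices and kernels), which curbs
the model's tendency to memorize training patients through the
high-dimensional gene latents instead of learning the generalizable
image texture. The rectifier nonlinearity is required for APoZ to be
meaningful.

## The dual-attention aggregator

Patch features are aggregated by a transformer encoder in the style used
for MIL: prepend a class token, apply a Nystrom-approximated multi-head
self-attention block, insert the pyramid position encoding generator
(PPEG: depthwise convolutions with kernels 3, 5 and 7 applied on the
square token grid and added residually; the token sequence is padded to a
perfect square by repeating leading tokens), apply a second attention
block, and read the normalized class token as the bag vector. Gene-set
latents pass through the same encoder *without* PPEG or padding, which
makes the gene branch permutation-invariant in its bag vector and
permutation-equivariant in its attention weights — both asserted in the
test suite, alongside the complementary assertion that the image branch is
*not* permutation-invariant once PPEG has nonzero kernels.

Nystrom attention approximates `softmax(QK'/sqrt(d))V` with `m`
segment-mean landmarks and a Moore-Penrose pseudo-inverse of the m x m
landmark kernel computed by a fixed 6-iteration Newton-Schulz scheme
(m = 8 by default for bags of at most 64 instances; both defaults are
package choices where the method family is silent). When `m >= n` the
implementation switches to exact dense attention, which is also the
oracle the approximation is tested against.

Cross-attention runs in both directions: the aggregated gene vector
queries the pre-aggregation patch features (keys/values), and the
aggregated image vector queries the gene-set latents. Each direction is
single-query multi-head dense attention. The four vectors — self-image,
self-gene, cross-image, cross-gene — are concatenated in that order into
a single linear classifier (two logits). An ablation flag (`self_only`)
drops both cross paths, shrinking the classifier input to 2D. All
learnable parameters — backbone, both encoders, both cross modules,
classifier — are optimized jointly with Adam on a cross-entropy loss,
one patient bag per step; the enrichment selection and the autoencoder
stay frozen, and a `freeze_backbone` flag reproduces the non-end-to-end
regime.

Exported attention weights are defined as the final attention block's
class-token row, computed densely (the Nystrom path approximates the
value aggregation, but the class-token row itself is cheap to compute
exactly), averaged over heads, with padded positions dropped and the rest
renormalized to sum to one. Which layer/head to report is not prescribed
by the method family; final-block head-averaging is this package's
declared convention.

## Interpreting gene-set attention

For the patients of a held-out split, per-gene-set attention weights
(self-gene or image-queried cross-gene) form a patients x sets table with
labels. Each set is tested for a class difference with the Mann-Whitney
U test (exact p for two groups both under 8 without ties, tie-corrected
normal approximation otherwise), corrected by Benjamini-Hochberg FDR, and
called significant below 0.01. "FDR-corrected" admits several procedures;
BH is the package's declared default. Significant sets get a follow-up
seeded label-permutation check: labels are shuffled with model and
features fixed, the statistic is the absolute difference in group mean
attention (a declared choice; the underlying procedure is described only
as recomputing group-wise differences), and the p-value is
`(1 + #(perm >= obs)) / (n_perm + 1)` with 999 permutations by default.
Spatially, patch attention is rendered by min-max scaling a bag's weights
and painting them at each patch's grid cell on a slide-shaped canvas,
with the top patch reported as the argmax (ties to the lowest
coordinate).

## Synthetic cohorts: what they emulate and what they do not

The generator produces the study conditions used throughout the tests:
slides are white backgrounds (intensity ~245) with dark elliptical tissue
blobs (~120, Gaussian-noised) cut at the field quantile matching a target
coverage of 0.5, so Otsu separation behaves as it does on stained tissue.
Within fully-tissue patch cells, a seeded fraction (default 0.6) carries
the class signal: dark nuclear-like spots at per-patch frequency 5
(class 0) versus 15 (class 1) — a texture deliberately learnable by a
small CNN. Expression is negative-binomial (dispersion 0.1) with
log-normal gene means; member genes of a designated 30% of gene sets are
mean-shifted by 2^1 in class 1, and the emitted adjusted-p table encodes
that known assignment (running a DE tool is out of scope). Defaults are
40 patients per class, 512-px slides, 64-px patches, 400 genes in 10
disjoint sets of 10-30 genes.

These fixtures validate mechanics — end-to-end learnability, attention
statistics, determinism — not histology. Real H&E texture, stain
variation, overlapping gene sets, correlated genes, batch effects and
label noise are all absent, so passing tests demonstrate that the
pipeline recovers signal it was designed to see, not clinical
performance.

## Evaluation protocol and problem sizes

Cohorts are split 80/20 stratified by class, with stratified five-fold
partitions of the training portion available for fold-level comparisons;
sensitivity, specificity and F1 use the argmax (0.5) threshold with the
positive class declared explicitly in configuration, while PR-AUC and
ROC-AUC are threshold-free (ROC-AUC via the rank formula, equal to
concordant-pair counting with ties at 1/2; PR-AUC by monotone-interpolated
precision summation). Paired t-tests compare fold-level metric vectors
and refuse zero-variance differences rather than returning NaN.

The shipped experiments use an 80-patient cohort, 16 patches of 64 px per
bag, D = 32, 2 heads, 8 landmarks, 12 training epochs at learning rate
1e-3 (batch = one bag; the general default of 1e-4 is conservative for
full-scale data, and the smaller synthetic problem tolerates the larger
rate), roughly four to five minutes per seed on one CPU. The pipeline's
determinism mode is simply its default: all randomness flows from the
configured seed through deterministic kernels, so identical
configurations reproduce result tables byte for byte.

## Known limitations

- The numerical core is a compact pure-R tape; it is adequate for the
  desk-scale problems shipped here but not for gigapixel cohorts on GPU.
- Pyramidal WSI formats are not read directly; slides enter as standard
  raster images (an adapter can be placed in front of the tiler).
- The autoencoder and enrichment inputs are fit once per cohort, not per
  fold; at the shipped scale this mirrors the frozen-upstream design but
  does leak unlabeled feature structure across the split.
- Attention weights are reported as model-emphasis measures only; no
  biological claim is attached to a significant set without external
  validation.
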