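# dualmil

Lightweight end-to-end multimodal multiple-instance learning (MIL) for
two-class tumor classification from histopathology whole-slide images
(WSIs) and gene-set level expression profiles, with attention-based
interpretability.

## Who this is for

Computational pathology / multi-omics researchers who want a compact,
fully inspectable implementation of the dual-attention multimodal MIL
recipe: a slide is a bag of patches, the transcriptome is a "bag" of
gene sets, and both bags are aggregated and fused by attention into a
single patient-level prediction. Everything — including the reverse-mode
autodiff engine behind the trainable modules — is plain R, so every step
from pixel to p-value can be read, seeded and unit-tested.

## The method

1. **Tiling & tissue filtering.** Slides are tiled into non-overlapping
   256-px patches (64-px at desk scale); a per-slide Otsu threshold
   separates dark tissue from bright glass; patches with > 90% tissue are
   valid; every patient contributes the same number of patches (the
   cohort minimum, e.g. 64).
2. **Reduced backbone.** Patch features come from a small mobile-style
   CNN made of universal inverted bottleneck (UIB) blocks. The ten
   removable blocks (stride 1, equal widths) are eliminated, and the
   final high-channel 1x1 convolution is pruned by APoZ (average
   percentage of zero activations), shrinking the pinned reference
   configuration from 340,992 to 68,880 parameters (~80%) — small enough
   to train jointly with the aggregator (end-to-end MIL).
3. **Gene-set branch.** Counts → TPM → log2(x+1); significant gene sets
   (adjusted p < 0.01 from upstream GSEA, consumed as GMT + p-value
   table) are zero-padded to a common width with a validity mask and
   compressed by a shared masked-MSE autoencoder to the image feature
   dimension D.
4. **Dual attention.** Each branch is aggregated by a Nystrom-attention
   transformer encoder (with pyramid positional encoding, PPEG, on the
   image side only); bidirectional cross-attention lets each modality's
   aggregated vector query the other's instance features. The four
   vectors (self-image, self-gene, cross-image, cross-gene) feed a linear
   classifier:

   `logits = W [ v_self_img ; v_self_gene ; v_cross_img ; v_cross_gene ]`

5. **Evaluation & interpretation.** Stratified 80/20 split with 5-fold CV
   utilities; sensitivity / specificity / F1 / PR-AUC / ROC-AUC; paired
   t-tests on fold values. Per-gene-set attention weights over test
   patients are tested with Mann-Whitney U + Benjamini-Hochberg FDR
   (p < 0.01) and validated by seeded label permutation; patch attention
   renders as slide heatmaps with top-patch extraction.

Synthetic multimodal cohorts (blobby tissue slides with class-dependent
spot texture; negative-binomial counts with mean-shifted gene sets) make
the whole pipeline testable without any download.

## Worked example

```r
library(dualmil)

cfg <- synthetic_cohort_config(seed = 101)     # 40 + 40 patients
co  <- simulate_cohort(cfg)
bags <- build_patch_bags(co$slides, co$labels, patch_size = 64,
                         max_budget = 16, seed = 101)
gb  <- gene_branch(co$counts, co$gene_lengths, co$gene_sets,
                   latent_dim = 32, epochs = 80, seed = 102)
bb  <- build_backbone(tiny_backbone_spec(32, 64), seed = 103)
mm  <- mil_model(mil_config(32, heads = 2, landmarks = 8), seed = 104)
sp  <- make_splits(co$labels, seed = 105)

fit <- train_model(mm, bb, bags$bags, gb$latents, co$labels,
                   patient_ids = sp$train_ids, epochs = 12, lr = 1e-3,
                   seed = 106)
pred <- predict_model(mm, bb, bags$bags, gb$latents, sp$test_ids)
str(evaluate_predictions(unname(co$labels[pred$patient_id]), pred$prob1))
#> List of 5
#>  $ sensitivity: num 0.875
#>  $ specificity: num 1
#>  $ f1         : num 0.933
#>  $ pr_auc     : num 1
#>  $ roc_auc    : num 1
```

The 16 held-out patients are ranked perfectly (both AUCs 1.0; one
positive falls on the wrong side of the 0.5 threshold) because the
synthetic cohort carries a strong, learnable signal in both modalities —
spot-texture frequency in the images and a 2-fold expression shift in
three designated gene sets. The point of the example is that the jointly
trained model recovers that signal from raw pixels and counts. Structural numbers of the pinned backbone:

```r
count_params(reference_backbone_spec("original"))  #> 340992
count_params(reference_backbone_spec("reduced"))   #> 68880
```

A YAML-driven pipeline (`validate_config()` / `run_pipeline()`, stages
simulate → tile → genes → train → eval → explain, with a thin CLI at
`inst/cli/dualmil.R`) orchestrates the same steps with provenance
manifests, JSONL logs and byte-reproducible result tables.

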