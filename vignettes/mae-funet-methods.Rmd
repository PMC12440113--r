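---
title: "Few-shot brain MRI analysis with masked-autoencoder transformers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot brain MRI analysis with masked-autoencoder transformers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Annotated brain MRI is scarce: cohorts are access-restricted, expert labels
are expensive, and acquisition protocols vary. A practical response is to
pretrain a vision transformer once, without labels, and then adapt it to
downstream tasks with very few annotated slices. `maefunet` implements that
workflow end to end in R:

1. **Coverage-weighted masked-autoencoder (MAE) pretraining.** A transformer
   encoder sees a random 25% of image patches; a lightweight decoder must
   reconstruct the hidden 75%. Learning to inpaint anatomy forces the encoder
   to build transferable representations of brain structure.
2. **Linear probing.** For MRI sequence identification (T1 vs T2 vs FLAIR
   ...), the frozen encoder's `[CLS]` embedding feeds a single affine
   classifier — `C * (d + 1)` trainable parameters, nothing else moves.
3. **MAE-FUnet segmentation.** For skull stripping and multi-class anatomy,
   a U-Net backbone is fused, at the bottleneck and every decoder stage, with
   the frozen encoder's per-layer token embeddings (concatenation, addition,
   or single-head cross-attention), trained with a compound
   Dice + Focal + cross-entropy loss.

All models run on a small reverse-mode autodiff engine written for this
package (`R/autograd.R`); there is no external deep-learning dependency. The
engine is validated against central finite differences in the test suite.

## The models and their losses

### Coverage-weighted reconstruction loss

For a batch of $N$ slices the pretraining loss is

$$\mathcal{L} \;=\; \frac{1}{N}\sum_{i=1}^{N} w_i\,\tilde l_i,$$

where $\tilde l_i$ is the mean squared error over the *masked* patches of
slice $i$ and $w_i \in [0,1]$ is that slice's brain coverage — the fraction
of pixels inside its binary brain mask, optionally floored
(`coverage_weight()`). Aggregated MRI cohorts contain many slices with
little or no brain (neck, vertex, padding); weighting by coverage keeps them
from dominating the objective. Two properties are load-bearing and tested:
the divisor is $N$ (not $\sum_i w_i$), and the loss depends on masked
positions only. The weight is the *raw linear* coverage fraction: it is the
simplest monotone choice, and it is isolated behind `coverage_weight()` so a
different schedule is a one-function change.

### Linear probe

The cross-entropy on raw logits $z$ with true class $y$ is
$\mathcal{L}_{ce} = -z_y + \log\sum_j e^{z_j}$, computed with log-sum-exp.
Following the customary linear-probing protocol, embeddings are standardized
with training-set statistics before the affine head; the statistics are
frozen constants, not trainable parameters, so the trainable count stays
$C(d+1)$ (at the full ViT-Base scale with an 8-unit head: $8 \times 769 =
6{,}152$). Evaluation is argmax with ties resolved to the lowest class
index; per-class accuracy is macro, overall accuracy micro.

### MAE-FUnet

The backbone is a standard U-Net: `depth` encoder levels of two 3×3
convolutions (each followed by a per-channel instance normalization and
ReLU), 2×2 max pooling between levels, channel widths doubling from
`base_dim`; a bottleneck block; and a mirrored decoder with nearest-neighbour
upsampling, a 3×3 convolution, skip concatenation and another conv block.
Instance normalization was chosen over batch normalization because training
operates sample-by-sample on a dynamic tape; it is deterministic and
batch-size independent.

Fusion happens at `depth + 1` points: the bottleneck plus every decoder
stage. The deepest selected encoder layer fuses at the bottleneck and
successively shallower layers at successively higher-resolution stages —
the standard semantic-depth alignment (at full scale, encoder layers
1/3/6/9/12 pair with decoder stages from full resolution down to the
bottleneck). At each point the layer's patch tokens (`[CLS]` excluded) are
reshaped onto their native grid, channel-projected by a learned linear map,
and bilinearly resized to the CNN resolution. The strategies:

* **concat** — channel-wise concatenation followed by a learned projection
  back to the CNN width, so downstream blocks are strategy-agnostic;
* **add** — element-wise sum;
* **attention** — single-head cross-attention with CNN pixels as queries and
  the (unresized) projected tokens as keys/values, residual-added. A single
  head with native-resolution keys keeps the attention matrix at
  $R^2 \times g^2$, which is what makes the module lightweight.

All three return the CNN feature shape and are drop-in interchangeable;
`fusion_strategy = "none"` yields the backbone-only U-Net used as the
paired baseline. The MAE weights are frozen throughout: their features are
computed once per slice and enter the tape as constants, so no gradient can
reach them by construction, and the test suite additionally asserts an MD5
digest of the encoder weights is unchanged by training.

**MAE-direct** is the contrast architecture: the frozen encoder's final-layer
tokens, reshaped to the patch grid and pushed through a convolutional
upsample-conv-norm-ReLU head to full resolution. It shares no spatial
information below patch resolution, which is why it trails the fused model.

### Hybrid segmentation loss

$$\mathcal{L}_{total} = \lambda_{dice}\mathcal{L}_{dice} +
\lambda_{focal}\mathcal{L}_{focal} + \lambda_{ce}\mathcal{L}_{ce},
\qquad \lambda_\cdot = 1.$$

* Soft Dice, per sample, all classes *including background*:
  $1 - (2\sum_i p_{i,c} g_{i,c} + \epsilon)/(\sum_i p_{i,c}^2 + \sum_i
  g_{i,c}^2 + \epsilon)$ averaged over $c$, with $\epsilon = 10^{-5}$. A
  class absent from both prediction and truth contributes exactly 0.
* Focal, $-\alpha(1-p_t)^\gamma \log p_t$ with $\gamma = 2$, $\alpha = 0.25$,
  mean over pixels; probabilities are clipped to $[10^{-8}, 1]$ before the
  logarithm, and the clipping is part of the contract (with $\gamma = 0,
  \alpha = 1$ it reduces to pixel-mean cross-entropy).
* Pixel-wise multi-class cross-entropy from logits via log-sum-exp.

### Metrics

Dice $= 2|P\cap G|/(|P|+|G|)$ and IoU $= |P\cap G|/|P\cup G|$, related by
IoU $=$ Dice$/(2-$Dice$)$. Both are defined as 1 when prediction and truth
are both empty — agreement on absence, the same degenerate case the Dice
loss guards with $\epsilon$. Dataset evaluation pools pixel counts per class
over the whole test set before scoring (micro aggregation, the default)
because per-slice averaging is unstable when a small class is absent from
many slices; `aggregate = "per_slice"` gives the alternative. Mean rows
exclude background. Sweep summaries report the sample (n−1) standard
deviation.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `mask_ratio` | 0.75 | fraction | the customary MAE ratio; high masking makes inpainting non-trivial |
| `clamp_low/high` | 0.1 / 99.9 | percentile | per-slice outlier clamp before min-max scaling |
| `target_size` | 224 (desk: 64) | pixels | full-scale slice side; desk preset keeps CPU runs in minutes |
| `patch_size` | 16 (desk: 8) | pixels | ViT-Base patching; desk grid stays 8×8 tokens at 64 px |
| `base_dim` | 64 | channels | U-Net initial width; 32/64/96 span the ablation axis |
| `fusion_layers` | 1,3,6,9,12 | layer idx | one per fusion point, shallow-to-deep |
| learning rate | 1e-4 (full) / 1e-3 (desk) | — | AdamW; the desk presets use fewer, larger steps |
| batch size | 48 (full) / 4–8 (desk) | slices | full-scale recipe vs CPU budget |
| `gamma`, `alpha` | 2.0, 0.25 | — | focal-loss emphasis on hard pixels |
| `epsilon` | 1e-5 | — | Dice smoothing; also defines the empty-class convention |

Masked-count rounding is half-away-from-zero, stated so the token counts are
reproducible. Positional embeddings are fixed 2-D sine/cosine (deterministic;
no learned table to initialize). The decoder follows the customary
lightweight sizing (512-dim, 8 layers at full scale) and is fully
config-exposed. Inputs are single-channel; the channel count is a config
field.

## The synthetic phantoms

Real pretraining cohorts are access-restricted, so the package ships a
seeded phantom generator that emulates exactly the data properties the
models consume:

* **multi-tissue geometry** — nested ellipsoids: skull rim, CSF layer,
  gray-matter shell, white-matter core, two elongated ventricles, and `k`
  (default 3) small deep structures strictly inside white matter. The
  ellipsoid family is deliberately minimal: it still produces the two
  difficulty axes that matter for segmentation — thin elongated regions and
  small blobs;
* **per-subject affine jitter** (scale, rotation, translation) so subjects
  differ;
* **pseudo-sequence contrast** — a tissue × sequence table whose orderings
  mimic T1/T2/FLAIR/PD (e.g. pT1: white > gray > CSF; pT2: CSF > gray >
  white), so sequence identity is learnable from intensities;
* **a smooth multiplicative bias field** — a low-order polynomial in
  normalized coordinates, mean-normalized to 1 (order 0 disables it
  exactly), preventing classifiers from keying on absolute intensity;
* **additive Gaussian noise**, and **variable brain coverage** along the
  axial axis (about a fifth of slices carry <10% brain), so the coverage
  weighting is genuinely exercised.

What phantoms do **not** emulate: anatomical realism, pathology, partial
volume effects, acquisition physics, inter-site heterogeneity. Passing the
phantom benchmarks therefore demonstrates that the machinery — losses,
freezing, fusion, the training loops — behaves as specified, and that
pretrained features help under a tiny annotation budget *on this family of
images*; it does not certify clinical segmentation accuracy, and the
headline accuracies published for real cohorts are not reproducible at desk
scale.

## Numerical choices and degenerate inputs

* Constant slices normalize to all zeros (flagged in provenance) instead of
  raising: aggregated cohorts contain empty slices, and the coverage weight
  already down-weights them.
* Argmax ties (prediction) resolve to the lowest class index.
* Stride sampling uses offset 0 and `ceiling((len - offset)/k)` slices per
  axis, which always includes the first slice and yields the exact doubling
  of slice counts between strides 10 and 5 on even-length axes. Nothing in
  the sampling is randomized.
* Isotropic resampling targets the minimum input spacing, scales each axis
  length by its spacing ratio (rounded to nearest), interpolates intensities
  linearly and labels/masks by nearest neighbour (no new labels can appear).
  Volume axes are taken in stored order; no anatomical reorientation,
  registration or bias-field correction is attempted.
* Percentiles for the clamp are computed per slice, matching slice-level
  preprocessing.
* All randomness derives from one master seed through named substreams
  (`substream_seed`), so data sampling, masking, initialization and
  augmentation are independently reproducible; identical seeds give
  bit-identical checkpoints.
* AdamW applies decoupled weight decay to weight matrices only (not biases
  or normalization gains).

## Desk-scale problem sizes

The shipped presets keep every experiment on one CPU in minutes, and they
are the sizes the test suite and `scripts/acceptance.R` run: pretraining on
500 phantom slices (64×64, 8×8 patches, 32-dim encoder, 4 layers) for 300
steps; segmentation with a depth-2, base-8 backbone fused at encoder layers
1/2/4, trained on 10 labelled slices for 300 steps and evaluated on 100
held-out slices from disjoint subjects; probing with 8 slices per sequence.
The few-shot benchmark trains every method on the identical subset with the
identical seed and budget — the comparison is paired by construction, and a
train/test subject overlap is a hard error.

## Known limitations

* The autodiff engine is tuned for clarity and desk-scale sizes, not for
  throughput; full-scale (224 px, ViT-Base) configurations are supported but
  slow on CPU.
* Per-layer token embeddings are taken from raw block outputs
  (pre-final-norm); `[CLS]` is taken after the final normalization.
* The probe's accuracy on phantoms is limited by how much sequence contrast
  survives into a tiny encoder's `[CLS]` token; it beats chance decisively
  but is far from the saturation reported for full-scale pretraining on
  real data.
* No surface-distance metrics, no significance testing between methods, no
  3-D convolutions, no test-time augmentation.
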