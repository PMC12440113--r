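# maefunet

Few-shot brain MRI analysis with masked-autoencoder (MAE) transformers, in R.

Annotated brain MRI is chronically scarce. This package implements a
three-stage workflow that gets strong task performance from a handful of
labelled slices:

1. **Self-supervised MAE pretraining** of a vision transformer on unlabelled
   2D slices, with a *brain-coverage-weighted* reconstruction loss

   L = (1/N) Σᵢ wᵢ·l̃ᵢ,

   where l̃ᵢ is the mean squared error over the masked patches of slice *i*
   and wᵢ ∈ [0,1] is the fraction of its pixels inside the brain mask, so
   slices dominated by non-brain content are down-weighted.
2. **Linear probing** for MRI sequence classification: the frozen encoder's
   `[CLS]` embedding feeds a single affine head trained with
   L_ce = −z_y + log Σⱼ exp(zⱼ); only C·(d+1) parameters are trainable
   (6,152 at full ViT-Base scale with an 8-unit head).
3. **MAE-FUnet segmentation** (skull stripping, multi-class anatomy): a U-Net
   backbone fused at the bottleneck and every decoder stage with the frozen
   encoder's per-layer token embeddings — by concatenation, addition, or
   single-head cross-attention — trained with the compound loss
   L = λ_dice·L_dice + λ_focal·L_focal + λ_ce·L_ce (all λ = 1,
   γ = 2, α = 0.25, ε = 1e−5). Evaluation uses Dice = 2|P∩G|/(|P|+|G|) and
   IoU = |P∩G|/|P∪G|.

Every model runs on a compact reverse-mode automatic-differentiation engine
included in the package (validated against finite differences in the test
suite); no external deep-learning framework is needed. NIfTI volumes are
read and written with RNifti; a seeded multi-tissue head-phantom generator
provides fully labelled synthetic data so the whole pipeline runs on one CPU
in minutes.

## Worked example

Pretrain a desk-scale encoder on 500 synthetic slices, then compare
MAE-FUnet against its backbone-only U-Net and an MAE-direct head, all
trained on the *same ten labelled slices* and evaluated on 100 slices from
disjoint subjects:

```r
library(maefunet)

slices <- make_pretrain_set(500, seed = 11)              # (image, brain mask) pairs
enc <- mae_init(vit_tiny_config(), seed = 11)            # 64 px, 8 px patches, 4 layers
enc <- mae_pretrain(enc, slices, steps = 300, batch_size = 8, seed = 11)

train <- make_segmentation_set(10,  seed = 21, subject_tag = "train")
test  <- make_segmentation_set(100, seed = 22, subject_tag = "test",
                               slices_per_subject = 10)
bench <- fewshot_benchmark(enc, train, test,
                           steps = 300, batch_size = 4, lr = 1e-3, seed = 21)
bench$summary
#>       method mean_dice  mean_iou trainable_params
#> 1  mae_funet 0.9771220 0.9552675            37490
#> 2       unet 0.9768960 0.9548354            32898
#> 3 mae_direct 0.9642495 0.9309670            29058
```

`mean_dice`/`mean_iou` are foreground (brain) scores pooled over the 100
held-out slices. With ten labelled slices all methods strip the phantom
skull well; the fused model leads, and the MAE-direct head — which sees the
image only at patch resolution — trails both U-Nets, the expected ordering.
The encoder is frozen throughout: `weight_digest(enc)` is identical before
and after training, and the fused model adds only the projection/fusion
weights to the U-Net's parameter count.

Sequence classification with the same frozen encoder:

```r
cls <- make_classification_set(8, c("pT1", "pT2", "pFLAIR", "pPD"), seed = 501)
head <- train_probe(enc, cls$samples, cls$manifest$class,
                    probe_config(4, enc$cfg$encoder_dim, learning_rate = 1e-2),
                    steps = 1500, seed = 1)
count_trainable(head)
#> [1] 132        # 4 x (32 + 1) at desk scale
```

## Command line

A thin Rscript wrapper exposes the pipeline as subcommands
(`phantom-gen`, `pretrain`, `probe-train`, `probe-eval`, `seg-train`,
`seg-predict`, `seg-eval`, `sweep`), each driven by a YAML config with
`--key value` overrides and each writing a reproducibility manifest:

```sh
Rscript inst/cli/maefunet.R pretrain --seed 2 --n_slices 200 --steps 100 --out ck/enc.rds
Rscript inst/cli/maefunet.R seg-train --encoder ck/enc.rds --method mae_funet --out ck/seg.rds
Rscript inst/cli/maefunet.R seg-predict --model ck/seg.rds --input t1.nii.gz --out pred.nii.gz
```

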