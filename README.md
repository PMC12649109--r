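# histoseg

Recall-first semantic segmentation for multi-organ histopathology patches.

In clinical screening a missed lesion (false negative) is far more costly
than a false alarm, yet most segmentation objectives optimise overlap scores
that trade the two symmetrically. `histoseg` implements a recall-prioritised
pipeline for binary lesion segmentation of histology patches:

- **Organ-conditioned encoder–decoder network.** A U-Net-style backbone with
  seven stages (widths 64, 128, 256, 512, 256, 128, 64), per-stage
  squeeze-and-excitation channel recalibration, and FiLM conditioning: each
  organ label *y* is embedded as *z* = Embedding(*y*) ∈ R³², and per stage
  *s* the features are modulated channel-wise as
  *F̃⁽ˢ⁾ = (1 + γ⁽ˢ⁾) ⊙ F⁽ˢ⁾ + β⁽ˢ⁾* with *γ⁽ˢ⁾ = σ(W_γ z + b_γ)*,
  *β⁽ˢ⁾ = W_β z + b_β*. An edge head (two 3×3 convolutions, three parallel
  dilated 3×3 convolutions with rates 1, 2, 3, two 1×1 convolutions) reads
  the last decoder features and predicts a boundary map. The network and its
  full backward pass are implemented on BLAS matrix operations, so the
  package trains on a plain CPU with no external deep-learning runtime.
- **Composite recall-prioritised loss.**
  *L* = 0.3·BCE + 0.7·Tversky(α = 0.3, β = 0.7), where the Tversky term
  1 − (TP+ε)/(TP + α·FP + β·FN + ε) penalises false negatives more than
  false positives; the total objective adds 0.4 × an edge BCE against
  morphological-gradient targets (Dilate(X) − Erode(X), both approximated by
  3×3 max pooling).
- **Entropy-driven human-in-the-loop fine-tuning.** Per-sample uncertainty
  is the mean binary entropy of the probability map; the top
  max(2, round(0.3·n)) samples per organ are selected and only the last two
  decoder stages, their FiLM maps and the output layer are fine-tuned
  (Adam, lr 2 × 10⁻⁴, weight decay 10⁻², 8 epochs, one-cycle schedule, EMA).
- **IHC weak-label pipeline.** Paired H&E / Melan-A immunohistochemistry
  regions of interest are rigidly aligned, cut into 512×512 patches at
  stride 256, and DAB (brown chromogen) masks are generated two ways — an
  HSV hue/saturation gate and a Ruifrok–Johnston stain-deconvolution channel
  with Otsu thresholding — then fused by logical OR, a deliberately
  recall-biased union.
- **Seeded synthetic data generator.** Pseudo-H&E / pseudo-IHC patch pairs
  and misaligned ROI pairs with exact ground truth, so every stage of the
  pipeline is testable without clinical data.

## Worked example

```r
library(histoseg)

# false-negative reduction: recall 0.8917 vs a 0.8701 baseline
round(100 * fnReduction(0.8917, 0.8701), 1)
#> [1] 18.6

# a scaled-down end-to-end run on synthetic data
sc <- synthConfig(imageSize = 32L, lesionRadius = c(4, 9), seed = 101L)
organs <- c("kidney", "liver", "spleen")
recs <- list()
for (org in organs) for (id in 0:15) {
  s <- generateSample(sc, org, id)
  recs[[length(recs) + 1]] <- sampleRecord(s@he, s@mask, s@organ, s@id)
}
model <- segNetwork(networkConfig(stageChannels = c(8L,16L,32L,64L,32L,16L,8L),
                                  embedDim = 8L, seReduction = 4L,
                                  inputSize = 32L), organs, seed = 1L)
tr <- trainModel(model, recs, recs,
                 trainConfig(maxEpochs = 10L, inputSize = 32L, seed = 1L))
tail(tr$history[, c("epoch", "total", "valRecall", "valDice")], 2)
#>    epoch     total valRecall   valDice
#> 9      9 0.7276131 0.7651851 0.5791998
#> 10    10 0.7000758 0.7731661 0.6164915
```

The `total` column is the training objective (composite segmentation loss
plus 0.4 × edge loss); `valRecall` is the fraction of lesion pixels
recovered at threshold 0.5, the metric used to keep the best checkpoint.
After ten epochs recall already sits ahead of Dice — the intended
recall-first behaviour; thirty epochs on this fixture take recall above
0.95 (the overfit-sanity check in the test suite). A full synthetic demonstration (generation,
augmentation, split, training, one human-in-the-loop round, per-organ
report) runs with:

```sh
Rscript inst/cli/histoseg.R demo --seed 1 --out demo-run
```

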