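---
title: "Recall-first organ-conditioned histopathology segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recall-first organ-conditioned histopathology segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoseg)
```

## The problem

Histopathology screening asks a different question of a segmentation model
than most benchmarks do: *did we miss anything?* A metastatic focus that is
small, weakly stained or blurred into surrounding tissue costs far more when
it is overlooked than a false alarm costs a reviewing pathologist. The
package therefore treats pixel recall as the primary objective throughout —
in the loss, in model selection, in the weak-label fusion rule and in the
evaluation reports — and accepts a deliberate cost in precision.

Two data regimes motivate the design. Public multi-organ nucleus/tissue
benchmarks supply images with manual masks, named `human_{organ}_{id}` so the
organ identity can condition the model. Clinical material often arrives as
*paired stains*: an H&E section showing morphology and a Melan-A
immunohistochemistry (IHC) section in which the brown DAB chromogen marks the
melanocytic cells directly. The IHC slide is effectively a noisy label for
the H&E slide — if the two can be aligned and the chromogen isolated.

## The model

The backbone is a symmetric encoder–decoder with seven stages of widths
(64, 128, 256, 512, 256, 128, 64): four encoder stages with 2×2 max-pool
downsampling (the fourth acting as bottleneck) and three decoder stages with
2×2 transposed-convolution upsampling and skip concatenation. Each stage is
a double 3×3 convolution + ReLU block, following the original U-Net
convention (no batch normalisation; at the training scales this package
targets the blocks are stable without it, and the backward pass stays
simple and exactly reproducible). Inside every stage, after the
convolutions:

1. **Squeeze-and-excitation.** Global average pooling gives one scalar per
   channel; a bottleneck MLP (reduction ratio 16 by default, a standard
   choice the source architecture leaves open) and a sigmoid produce a gate
   in (0,1) per channel, multiplying the features. This lets the network
   amplify lesion-salient channels against background texture.
2. **FiLM organ conditioning.** Each organ label is a learned 32-dimensional
   embedding $z$. Per stage, linear maps give
   $\gamma = \sigma(W_\gamma z + b_\gamma)$ and $\beta = W_\beta z + b_\beta$,
   and features transform as $(1+\gamma)\odot F + \beta$ — a channel-wise
   affine whose scale is confined to (1, 2) by the sigmoid. With zero
   parameters this is exactly a 1.5× scale, independent of the organ; the
   package initialises the FiLM maps at zero so conditioning grows from a
   neutral start. The order convs → SE → FiLM (conditioning applied to the
   recalibrated channels) is a package choice; the source design attaches
   both per stage without fixing an order.

The output head is a 1×1 convolution plus sigmoid; thresholding at 0.5
happens only at evaluation. An **edge head** reads the last decoder features:
a two-layer 3×3 stem, three parallel 3×3 convolutions with dilation rates
1, 2, 3 (padding equal to dilation, so shape is preserved), concatenation,
and two 1×1 convolutions to a single sigmoid channel. Internal widths
(stem 64→32→32, branches 32→32, fusion 96→32→1) are package choices. Edge
supervision targets come from the mask's morphological gradient,
Dilate(X) − Erode(X), with both operators approximated by 3×3 stride-1 max
pooling — the formulation stays differentiable. Border semantics: dilation
treats out-of-frame pixels as background and erosion treats them as
foreground, so a mask running off the image edge produces no spurious
border edge.

The whole network, including the backward pass, Adam, the one-cycle
schedule and EMA, is implemented on base BLAS matrix operations (im2col
convolutions). Every gradient path was verified against central finite
differences during development; the test suite checks the layer contracts
against closed-form oracles.

## Losses

With $\hat y$ the predicted probability and $y$ the mask, all estimators
pool pixels over the whole batch (the batch-pooled reading of the loss
definitions; a per-image average is the natural alternative and the choice
is documented here because the formulas are ambiguous about it):

- Binary cross-entropy, clamped at $10^{-7}$ before logs.
- Tversky loss $1 - \frac{TP+\epsilon}{TP + \alpha FP + \beta FN + \epsilon}$
  with soft counts, $\alpha = 0.3$, $\beta = 0.7$, $\epsilon = 10^{-6}$ (the
  smoothing constant's magnitude is unstated in the source; $10^{-6}$ keeps
  the worked examples accurate to $10^{-6}$). $\beta > \alpha$ makes a
  missed positive cost more than a false alarm — the recall bias is
  mechanical, and a test asserts the gradient magnitude ordering directly.
- The composite segmentation loss 0.3·BCE + 0.7·Tversky, and the total
  objective 1.0·composite + 0.4·edge-BCE.

## Training and model selection

Adam at $5\times10^{-4}$, batch 8, up to 50 epochs, inputs resized to
224×224 (bilinear for images, nearest for masks so they stay binary).
After every epoch the model is evaluated on the held-out split at threshold
0.5 and the checkpoint with the highest validation recall is kept. Because
recall is the selection metric, the kept model can be an early, liberally
segmenting epoch; that is the intended recall-first behaviour, not an
accident. The held-out test split doubles as the validation set — the
source protocol reports no third split — which is a documented caveat, not
a recommendation for real deployments.

## Human-in-the-loop stage

The offline HITL stage simulates expert triage: (1) predict on the pool and
score each sample by the mean per-pixel binary entropy (nats; the base only
rescales the ranking), (2) per organ select the top
$k = \min(n, \max(2, \mathrm{round}(0.3\,n)))$ samples (round half up; ties
broken by ascending sample id so selection is order-independent),
(3) fine-tune with only the last two decoder stages — their upsamplers,
conv blocks, SE blocks and FiLM maps — plus the 1×1 output layer unfrozen
(the edge head and the embedding table stay frozen; the freeze set is
asserted tensor-by-tensor in the tests), using Adam with decoupled weight
decay $10^{-2}$ at peak learning rate $2\times10^{-4}$ for 8 epochs under a
one-cycle schedule, with an EMA (decay 0.999, a conventional value the
source does not state) of the unfrozen weights applied to the returned
model. Whether uncertainty should be scored on the training pool or a
held-out pool is ambiguous in the source description; the package scores
the pool it is given, and the demo passes the training pool.

## Weak labels from paired stains

`alignPair` applies a rigid rotation about the image centre followed by a
translation, resampling bilinearly (nearest for masks) with white fill —
slide background — outside the frame. `extractPatches` cuts 512×512 windows
at stride 256 on a half-open, top-left-anchored lattice, dropping windows
that would overrun the frame; the count is
$(\lfloor (H-512)/256 \rfloor + 1)(\lfloor (W-512)/256 \rfloor + 1)$, which a
property test checks against brute-force enumeration. On the default
1500×2100 ROI geometry this gives 4 × 7 = 28 patches.

Two candidate DAB masks are generated per patch. The HSV gate keeps pixels
with hue in 15–45° (DAB brown), hue outside 180–260° (the haematoxylin
counterstain), saturation ≥ 0.15 and value ≤ 0.98, then applies
opening/closing (radius 2) and drops components under 64 px. The HED mask
deconvolves RGB optical density through the standard Ruifrok–Johnston
H/E/DAB basis, blurs the DAB channel (σ = 2 px), Otsu-thresholds the
min–max rescaled channel, cleans up morphologically and fills holes; a
shift-invariant bimodality gate (foreground/background OD contrast
≥ 0.08) returns an empty mask on signal-free patches where Otsu would
merely split noise. All thresholds are package calibrations — the source
pipeline reports none — and all are exposed in `maskGenConfig`. The final
weak label is the logical OR of the two candidates: union fusion can only
add positives, matching the recall-first rationale, and a test asserts the
fused mask dominates each candidate.

## The synthetic data generator

`generateSample` builds, per (seed, organ, id) — the RNG stream is keyed by
the triple, so generation is order-independent and bit-reproducible:

- a lesion mask as a union of perturbed ellipses (boundary radius modulated
  by low-order harmonics), redrawn until coverage lies in [1%, 50%];
- a pseudo-H&E rendering: haematoxylin-toned textured background with
  eosin blotches and a *subtle* lesion contrast (per-organ intensity,
  texture scale and contrast differ via the organ style table), so that
  segmentation from H&E alone is non-trivial;
- a pseudo-IHC rendering: DAB brown strictly inside the configured hue band
  (20–40°) on lesion pixels only, over a pale blue counterstain, with
  seeded stain jitter.

`generateRoiPair` renders an aligned scene at the 1500×2100 ROI geometry
and displaces the IHC by the inverse of a known rigid transform (|deg| ≤ 15,
|dx|,|dy| ≤ 200, the plausible manual-alignment range), so the recorded
transform restores alignment by construction.

What the generator does *not* emulate: realistic nuclear texture, stain
spill-over between chromogens, out-of-focus regions, tissue folds, or
instance-level ground truth. Passing tests therefore demonstrate that the
pipeline's machinery is correct and recall-biased under controlled
conditions; they do not certify performance on clinical slides.

## Study sizes used by the test suite

The deep-learning stack runs on a single CPU, so the test suite exercises
the full pipeline at reduced scale, chosen once: 32×32 patches, stage
widths (8, 16, 32, 64, 32, 16, 8), embedding dimension 8, SE reduction 4,
three organs × 16 images, 30 training epochs. At 32×32 the generator's
scale-relative default lesion radius (size/16 to size/6) would produce
2-pixel lesions at the resolution limit; since the end-to-end check is an
*overfit-sanity / capacity* test on separable data, the training fixtures
set the lesion radius to 4–9 px (a 12–28% linear fraction, comparable to
metastatic foci in ROI crops) so lesions stay resolvable after downscaling.
All scientific hyperparameters — learning rates, batch size, loss weights,
HITL ratio and floor, epochs — remain at their published defaults. The
demo subcommand uses the same reduced geometry.

## Numerical choices and degenerate inputs

- Probability clamp $10^{-7}$ before any logarithm.
- Metrics on an image with empty ground truth: 1.0 if the prediction is
  also empty, else 0.
- Otsu on a constant DAB channel is undefined: the HED generator warns and
  returns an empty mask.
- An organ with a single source image cannot be split 8:2; it goes to train
  with a warning. Split rounding is towards train (ceiling), capped at
  n − 1 so every organ with ≥ 2 sources appears in both splits; splitting
  happens at source level, before augmentation, so augmented copies never
  straddle the split.
- Greyscale conversion uses the 0.299/0.587/0.114 luma weights; colour
  jitter draws brightness/contrast/saturation offsets from U(−0.1, 0.1),
  seeded.
- The all-zero-difference case of the paired Wilcoxon test is reported as
  NA, and a constant non-zero shift (zero variance) leaves the paired t
  statistic undefined (NA) with the exact mean difference reported.

## Known limitations

- The parameter count of the full-size configuration is 7.9 M; the source
  architecture's printed 9.79 M cannot be reconstructed from its text (SE
  ratio, block depth and edge-head widths are unstated there), so the count
  is reported, never asserted.
- Training at the full 224×224 / 64–512-channel scale is possible but slow
  on CPU; the package is written for methodological fidelity and testability
  at desk scale, not throughput.
- The offline HITL stage substitutes entropy ranking for real expert
  corrections; it demonstrates the selection-and-refinement mechanism, not
  human–AI collaboration.
- How the source's 37 clinical ROIs become exactly 189 augmented images is
  arithmetically underdetermined (a non-integer ×5.11); the package exposes
  the augmentation operation list instead of hard-coding any factor.
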