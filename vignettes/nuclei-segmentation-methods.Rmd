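---
title: "Methods: deformable-aggregation segmentation of cervical nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deformable-aggregation segmentation of cervical nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the choices behind it, the synthetic
data it is tested on, and the numerical details a maintainer needs. Code
chunks are illustrative and not evaluated at build time; everything shown
is exercised by the test suite.

## The segmentation problem

Clustered cervical nuclei are small, mutually adherent, and irregularly
outlined; the foreground can be a tiny fraction of the image (down to the
order of 0.01% on clustered-slide material). Two failure modes drive the
architecture: fixed-patch embeddings destroy boundary structure, and
uniform attention spends its capacity on background.

## Model

### Multi-receptive embedding

`multi_kernel_embed()` runs several strided convolutions with *same-centre*
padding `(size - stride) / 2` so every branch sees patches centred on the
same locations, at different receptive sizes, and produces the same token
grid; branch outputs are concatenated. `allocate_dims()` gives smaller
kernels more channels because convolution cost grows as $K^2 D^2$: with
four kernels the split is $D/2, D/4$ and the last two kernels share the
remaining $D/4$; with two kernels the split is $2D/3$ rounded to the
nearest multiple of a head width of 4. No canonical split is forced by the
cost argument alone, so the rule is configurable; the default respects
"smaller kernels get more dimensions". Stage 1 uses kernels (4, 8, 16, 32) at
stride 4 — the choice consistent with same-centre padding and a stride-4
stem; stages 2-4 use (2, 4) at stride 2, which quarters the token count.

### The adaptive pixel adjustment operator

The core operator (module `deform_core`) computes, per output position
$p_0$ and group $g$,

$$y_g(p_0) = w_g \sum_{k=1}^{K} m_{gk}\; x_g\!\left(p_0 + p_k + \Delta p_{gk}\right),$$

with a fixed centred $3\times3$ grid $p_k$ (`build_sampling_grid()`),
continuous learned offsets $\Delta p_{gk}$, modulation scalars $m_{gk}$
softmax-normalized over $k$ (`normalize_modulation()`, computed in the
max-shifted log-sum-exp form and exponentiated, so every (group, position)
sums to 1), bilinear sampling with a zero border (`bilinear_sample()`),
and a per-group $C' \times C'$ point projection with $C' = C/G$. Group
outputs are concatenated along channels. `brute_force_aggregate()` is the
literal triple-loop definition and serves as the oracle for the compiled
vectorized path; the two agree to machine precision in the tests.

Design points that were genuinely open:

* **Sigmoid vs softmax for the modulation.** Earlier deformable operators
  normalize each modulation scalar independently with a sigmoid; here the
  binding contract is that the K scalars of a group sum to one, which a
  sigmoid cannot guarantee, so the modulation is a softmax over the K grid
  points. The log-softmax form is used for stability and exponentiated —
  the sum-to-one contract forces the exponentiation.
* **Meaning of the ROI extent (w, h).** Undefined for a dense backbone; we
  take the current stage's feature-map width and height, so the clamped
  amplitude $\gamma \in [0.01, 0.5]$ bounds the reach to at most half the
  map — consistent with the long-range-dependency motivation. It is a
  per-layer learnable scalar (not per group), hard-clamped (not
  reparameterized), initialized at 0.1; the gradient passes only strictly
  inside the clamp box.
* **Offset component pairing.** Offsets are stored (Δrow, Δcol); the
  column component scales with the horizontal extent w and the row
  component with the vertical extent h.
* **The offset/modulation predictor** is a 3×3 depthwise + 1×1 pointwise
  convolution emitting $3GK$ maps (two offset components and one
  modulation per group-point). The pointwise weights are initialized with
  a tiny standard deviation ($10^{-3}$) rather than exactly zero: the
  block still starts arbitrarily close to the static separable-convolution
  limit (offsets ≈ 0, modulation ≈ uniform), but every parameter —
  including the depthwise filter and γ — receives a nonzero gradient from
  the first step, which an exact-zero initialization would block.

### Backbone and decoder

Stages 1-2 are pre-norm window-attention blocks (window 7 at full scale, 4
in the tiny preset) alternating un-shifted and half-window cyclically
shifted windows; the shifted blocks use no attention mask and no relative
position bias — simplifications documented here deliberately, acceptable
at these window sizes. Stages 3-4 are APAB blocks only (MLP ratio 4,
pre-norm). Published depth/width tables are not available, so two presets
are shipped as YAML (`inst/presets/`): `paperlike` (depths 2,2,6,2, dims
96,192,384,768, decoder width 256) mirrors common 4-stage backbone
practice at full scale; `tiny` (depths 1,1,2,1, dims 16,32,64,128, decoder
width 64) is the CPU test configuration. The decoder is UperNet-shaped:
pyramid pooling at scales {1,2,3,6} on the stage-4 map, lateral 1×1
projections, top-down upsample-and-add, 3×3 smoothing, concatenation at
the finest (stride-4) grid, a fused 3×3 conv, and a 1×1 classifier
upsampled bilinearly to the input. Decoder convolutions use token-wise
LayerNorm + ReLU (the canonical decode head uses BatchNorm; LayerNorm is
batch-size-independent and keeps CPU runs deterministic at batch 2).

### Autodiff substrate

All layers run on a small tape-based reverse-mode engine (`R/autograd.R`):
eager ops record nodes on a tape; one reverse sweep propagates gradients.
The heavy kernels — im2col/col2im convolution, depthwise convolution,
grouped deformable bilinear aggregation (forward and backward), bilinear
resizing and connected-component labelling — are C++ (`src/kernels.cpp`).
Every primitive is finite-difference-checked in the tests.

## Training and evaluation

`train_config()` defaults to the reference protocol: batch 2, SGD with
learning rate 0.001 (constant schedule; a decaying schedule was considered
and left out since only the initial rate is specified), momentum 0.9,
weight decay 0.0005, crop 224. The loss is
$w_{ce}\,\mathrm{CE} + w_{dice}\,(1 - \frac{2\sum p t + 1}{\sum p + \sum t + 1})$
with the stated weight ratio of 3; which side carries the 3 is not
specified, so the default is CE:Dice = 1:3 (emphasizing overlap under
foreground scarcity) and both weights are exposed. Evaluation binarizes by
argmax (no threshold is stated anywhere), and dataset metrics pool
TP/FP/FN/TN over all images before applying the formulas
(micro-averaging); per-image macro-averaging is available. The Dice–IoU
identity $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ holds exactly
for pooled counts and is fuzz-tested.

`gradcam_map()` weights a layer's 2D activations by the spatially averaged
gradient of the summed foreground logit, rectifies, selects the
maximum-value channel, min-max normalizes and upsamples. The default
target layer is the decoder's fused convolutional map — the last
convolutional layer before the classifier, the standard Grad-CAM choice.
Backbone stages are selectable, but their LayerNormed residual streams
carry dense background structure that violates Grad-CAM's assumption of
class-discriminative sparse activations, and they localize measurably
worse; the gradient field itself is sharply localized at the nuclei, so
the limitation is the activation prior, not the gradients.

## Synthetic scenes

`generate_scene()` emulates the structure of clustered cervical material:
nuclei are ellipses whose radius is perturbed by a truncated 8-harmonic
Fourier series with amplitudes proportional to roughness/harmonic (smooth,
controllable "rough edges"), placed around cluster centres with jitter;
with probability `overlap_prob` a nucleus is placed against an existing
one and the scene is only accepted when their masks actually touch
(adherent pairs by construction). Nuclei are stained darker than a
textured background and the scene gets additive Gaussian noise. The
foreground fraction is driven into the spec's band by rejection
resampling; an infeasible band errors out up front.

Two specs are shipped. The default training spec (64×64, 1-4 nuclei of
radius 2.5-6 px, foreground 2-6%) relaxes the real-world scarcity so
micro-training converges on a CPU in hundreds of steps. The
`scene_spec_scarce()` spec (1024², foreground 0.005-0.02%) reproduces the
extreme scarcity regime and is used for imbalance stress tests only. What
passing tests on these scenes shows: the operator/loss/optimizer stack can
learn boundary-accurate foreground separation from scratch. What it does
not show: performance on real stained cytology, where texture, stain
variability, focus and cytoplasm context are far richer than this
generator emulates.

## Problem sizes used by the tests

The suite runs on one CPU in a few minutes: the operator oracle uses 20
random instances on maps up to 8×8; finite-difference checks use maps of a
few dozen tokens; micro-training uses 200 scenes of 64×64 for 600 SGD
steps with 50 held-out scenes; Grad-CAM localization uses 10
single-nucleus scenes; determinism compares two 50-step CLI runs bitwise.
The boundary-roughness monotonicity check averages 30 seeds per roughness
level.

## Known limitations

* **The single-image overfit floor.** With CE:Dice = 1:3, the loss is
  dominated by the soft-Dice term. Logits live on the stride-4 grid and
  are bilinearly upsampled, so a roughly one-pixel-wide soft band along
  every nucleus boundary is irreducible until logit magnitudes become very
  large; for default-spec nuclei (radius 2.5-6 px) this puts a floor of
  about 0.2 on the combined loss over a few hundred SGD steps even though
  the *hard* mask is already near-perfect (IoU ≈ 0.92 on the overfit
  image, CE ≈ 0.01). Driving the combined loss below 0.05 in 200 steps at
  learning rate 0.001 is therefore out of reach at these scene scales, and
  the corresponding test documents this honestly by failing.
* No ImageNet pretraining, no GPU path, no mixed precision, no
  distributed training; full-scale (360k-iteration) runs are out of scope.
* The window attention omits the shifted-window mask and relative position
  bias (see above).
* Checkpoints are R serializations with a config fingerprint; they are not
  portable to other frameworks.
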