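---
title: "angioflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{angioflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Digital subtraction angiography (DSA) acquires an X-ray image sequence
during contrast passage; a pre-contrast mask is subtracted so vessels
appear as dark structures on a light background. Radiation dose is
proportional to the number of frames acquired at fixed exposure
parameters. If a model can synthesize the frames between two acquired
frames, the scanner can acquire only one real frame per block of
N + 1 frames and generate the N interior frames, reducing dose to
1/(N+1) — 1/7 (an 85.71% reduction) at the clinically interesting
N = 6.

`angioflow` implements this program at desk scale: a procedural
angiography simulator with exact ground truth stands in for clinical
data; a compact flow-guided interpolation network, its composite loss
and optimization schedule, the sparse acquisition/reconstruction
pipeline, the image-quality metrics, and the reader-study statistics
are all implemented and tested end to end.

## The simulator: a stated world

The simulator's job is to emulate the *structure* of DSA sequences —
not anatomy. Its choices, fixed once:

* **Vessel trees** grow in a unit cube: a tapering trunk plus side
  branches. Child radii follow a Murray-law-like taper (×0.79 with
  −10% jitter); along-vessel taper is at most 4% per segment. Radii are
  in pixels at a 128 px reference domain. Bolus arrival time increases
  with path length from the root (speed 0.12 cube units/frame, giving
  arrival spreads of several frames across a tree — comparable to the
  wash-in of a real injection at ~3 frames/s).
* **Disease-like morphologies**: a saccular aneurysm (a disc-rendered
  bulge at a junction, 2.2× the parent radius), a focal stenosis (a
  mid-trunk segment split into pre/narrow/post with the narrow radius
  0.4× the lumen — below half of *both* neighbours), an AV-shunt (a
  thin direct connection between an arterial node and a distal venous
  node, radius 0.6 px, early arrival), and a collateral network (a
  dense subnetwork of ~0.5 px segments). One structural conflict in
  the contracts is resolved in favour of the clinical picture: a
  stenosis must recover its lumen distally, so the child-radius taper
  invariant is not enforced across the narrowed segment itself.
* **Contrast dynamics** follow the gamma-variate curve, the standard
  parametric bolus model:
  $c(t) = \left(\frac{t - t_0}{t_p}\right)^{\alpha}
  \exp\!\left(\alpha\left(1 - \frac{t - t_0}{t_p}\right)\right)$ for
  $t > t_0$, else 0. The peak equals exactly 1 at $t = t_0 + t_p$,
  which the tests exploit as a closed-form oracle. Defaults
  $t_p = 4$ frames, $\alpha = 2$.
* **Rendering**: segments are rasterized as anti-aliased capsules
  accumulating optical density (clipped at 0.6 so overlaps saturate),
  subtracted from a smooth low-frequency background (level 0.85 ± 3%)
  with Gaussian noise (σ = 0.01). Vessels are dark, per clinical
  display convention; an `invert` flag flips it. 3D mode rotates the
  tree about the vertical axis with per-frame angles uniform on
  [0°, 180°] and projects orthographically — the simplest geometry
  that produces projection deformation and vessel-overlap dynamics.
* **Guidewire**: a fixed smooth spline path entering from the image
  edge; the visible portion advances at constant arc length per frame,
  and the recorded ground-truth tip is the distal endpoint of the
  drawn polyline. The capsule rasterization's rounded cap keeps the
  skeletonized tip within about one pixel of the recorded one, which
  is the localization tolerance the tests assert.
* **Artifacts**: the affected region is the top `severity` fraction of
  a seeded smooth random field, so the affected-pixel fraction is
  monotone in severity and severity 0 is a bit-exact no-op. "Motion"
  resamples the region from a smoothly displaced copy; "subtraction
  ghost" adds a bright low-frequency residual, as incomplete mask
  subtraction does.
* **Frame times** are integer frame indices; the source protocol never
  states a frame rate.

What the simulator does **not** emulate: anatomy (no atlas), photon
transport and kerma physics, detector blur/lag, and the appearance of
real thoracic guidewire navigation. A green test therefore establishes
that the *algorithmic chain* behaves as specified on sequences with
DSA-like structure, not that clinical image quality is reproduced.

## Preprocessing

Images are padded symmetrically to square with the image minimum
(background is the maximum under the dark-vessel convention, so the
pad is recognisably vessel-free), resized bilinearly (half-pixel
centers), and min-max normalized to [−1, 1] per frame; a per-sequence
mode preserves relative intensities over time and is what the pipeline
uses when time-intensity fidelity matters. A constant image normalizes
to all zeros. Timesteps are $t_i = -1 + 2i/(n-1)$: −1 and +1 are the
real endpoint frames, interior frames are the synthesis targets.

## The network

The architecture follows the published outline — multi-scale encoder
and decoder with direction-aware convolution blocks, a bidirectional
optical-flow module with coarse-to-fine refinement, and a
spatio-temporal attention bottleneck — with the under-specified
internals declared here:

* **DACB**: one 3×3 branch per orientation in {0°, 45°, 90°, 135°},
  each kernel masked to the line through its center at that angle
  (masked taps contribute exactly zero, enforced by multiplying the
  weights with a 0/1 mask in the graph so gradients cannot revive
  them); branches are concatenated and fused by a 1×1 convolution. All
  branches share one im2col/GEMM — they see the same input — which is
  an implementation detail, not a semantic one.
* **Channel widths** are `base_channels × 2^s` (16 doubling per the
  protocol; the desk-scale test model uses base 8).
* **Flow**: two backward-sampling fields, one into each endpoint
  frame, both targeted at time t. The coarsest scale predicts from the
  concatenated encoder features plus a constant-t channel; each finer
  scale upsamples ×2, scales ×2, warps that scale's features, and
  predicts a correction. Warping is backward bilinear with border
  clamp; flow heads are initialized near zero so the initial model is
  a 50/50 blend at zero displacement.
* **STFB**: a single multi-head self-attention layer (4 heads) over
  the tokens of *both* warped coarse feature maps jointly — intra- and
  inter-frame attention in one pass — with a learned positional table
  (created at training time, when the bottleneck size is known; an
  untrained model falls back to a fixed sinusoidal table) and learned
  frame-identity embeddings, followed by a 1×1 fusion convolution.
* **Synthesis**: the decoder (with warped-feature skip connections and
  a DACB at the finest scale) predicts a sigmoid fusion mask α and a
  residual r; the output is
  $\tanh\!\big(1.25\,(\alpha I_0^w + (1-\alpha) I_1^w + 0.2\,r)\big)$,
  bounded to [−1, 1]. The residual is deliberately weak (×0.2):
  with a strong residual path the flow stalls at roughly half the true
  displacement, because a symmetric pair of under-estimated flows
  preserves the phase of low-frequency content and the residual
  repairs the amplitude. Weak residual + fine-scale image content make
  misalignment expensive, and the flow then converges to the true
  displacement (the translation diagnostic in the test suite measures
  this directly).

Reverse-mode differentiation is a small in-package tape over dense
arrays with C++ kernels (im2col GEMM convolution with cached
workspaces, bilinear warp with gradients to both source and flow).
Everything is double precision and single-threaded; forward passes are
bit-deterministic given fixed weights.

## Objective and schedule

$L = \alpha\,\mathrm{mean}|p - t| + \beta\,(1 - \mathrm{SSIM}(p,t))
+ \gamma \sum_l \mathrm{mean}|\phi_l(p) - \phi_l(t)|
+ \delta \sum_l \mathrm{mean}(\phi_l(p) - \phi_l(t))^2$

with weights (1, 1, 0, 0) for the first 50 epochs and
(0.5, 0.7, 40, 40) thereafter. The structural term is 1 − SSIM
(no ÷2); inputs are shifted to [0, 1] before SSIM and the perceptual
terms because the SSIM stabilizing constants assume a non-negative
dynamic range. The perceptual extractor is a fixed, seeded,
randomly-initialized 3-stage strided CNN standing in for a pretrained
backbone — no download, flagged as such — with features taken after
every stage. AdamW (decoupled weight decay 0.01) with
$lr = lr_{\min} + \tfrac12(lr_0 - lr_{\min})(1 + \cos(\pi e/P))$,
$lr_0 = 10^{-4}$, $P = 50$, $lr_{\min} = 10^{-18}$; the ambiguous
"50-epoch period" is implemented as warm restarts by default with the
single-anneal reading behind `lr_restart = FALSE`. Batch size 8 for
N ≤ 6 (4 for N ∈ {7, 8}) via gradient accumulation. Scaled-down runs
(e.g. 30 epochs) set `phase1_epochs = total_epochs`: they end before
the epoch-50 switch, so the whole run is phase 1 — which also keeps
the "final loss < first loss" diagnostic meaningful, since the two
phases' losses are on different scales.

## Sparse pipeline

`subsample()` keeps frames {0, N+1, 2(N+1), …} plus the final frame
(a clinical sequence ends on a real frame, so a trailing partial block
retains its real endpoint). `reconstruct_sequence()` synthesizes
interior frame i of block (a, b) at timestep −1 + 2(i−a)/(b−a) — the
same grid `assign_timesteps()` produces — with a pluggable
interpolator: the trained model or the closed-form linear blend that
serves as oracle and baseline. Real frames pass through bit-exact.
Blocks are strictly two-endpoint; whether a clinical protocol would
condition on more context is unknowable from the source and noted as
out of scope.

## Evaluation

SSIM uses the canonical Gaussian-window form (11×11, σ = 1.5,
K1 = 0.01, K2 = 0.03, data range 1.0, valid windows); PSNR uses
peak 1.0 so PSNR = −10 log10 MSE, with identical images reported as
∞. Confidence intervals are percentile bootstrap over *sequences*
(1000 reps, seeded) — the CI construction is unstated in the source
and declared here. Time-intensity error normalizes each pixel's
temporal series to [0, 1] independently per sequence and takes the
maximum absolute difference, making it invariant to per-pixel affine
distortions. Guidewire tip localization thresholds the darkest pixels,
confirms the largest connected component is curvilinear via its
Zhang-Suen skeleton, and takes the tip as the sub-pixel centroid of
the component's geodesically farthest end cap from the entry point
(the component pixel nearest the image border). Working on the
component rather than the skeleton endpoints matters: thinning erodes
line ends by 1-2 px, which alone would exceed the 1 px localization
tolerance the tests assert. Frames with no curvilinear structure are
flagged and excluded from the mean rather than scored.

## Reader statistics

Turing-test confusion matrices report accuracy plus *both* per-class
recalls explicitly (the source's "sensitivity and recall" are synonyms
under the usual definitions; which class each referred to is
unstated). Fleiss' kappa uses the standard marginal formulation and
returns a sentinel with explanation when every rating falls in one
category (chance agreement 1, kappa undefined). Inter-observer kappa
is weighted Cohen's kappa, quadratic by default for the 5-level
ordinal scale. The Wilcoxon signed-rank test drops zero differences,
mid-ranks ties, enumerates all 2^n sign patterns exactly for n ≤ 12,
and uses a tie-corrected normal approximation with continuity
correction above. Rating summaries use the sample (n−1) standard
deviation. Raw P-values at α = 0.05; no multiplicity correction, as in
the source.

## What the tests establish

The acceptance suite checks (a) closed-form protocol numbers — dose
arithmetic, the 200-pair reader-study design, schedule values — at
exact tolerances, and (b) behavioural properties: oracle equivalence
of warping and the rank statistics against brute-force enumeration,
pipeline conservation over every (L ≤ 40, N ≤ 8), and a stochastic
learning-efficacy criterion: a tiny model (base 8 channels, 64×64,
200 synthetic sequences, 30 epochs, fixed seeds) must beat the linear
blend baseline in held-out SSIM at N = 1 and N = 6 and beat the
frame-repeat baseline in time-intensity error. Clinical-scale headline
numbers for this family of methods (SSIM ≈ 0.95, PSNR ≈ 40 dB, reader
agreement statistics) require private multicenter data and full-scale
weights and are explicitly out of reproduction scope.

## Known limitations

* The simulator's realism ceiling: no anatomy, no detector physics, no
  real guidewire appearance model.
* The architecture reconstructs supplementary-only internals from
  declared defaults; it is a faithful *kind* of model, not a weight-
  level reproduction, and its parameter count is far below the
  original.
* Training at desk scale is hundreds of sequences for minutes, not
  17k sequences for 1000 epochs; conclusions from the green
  learning-efficacy test are directional (the method beats its
  baselines on the stated world), nothing more.
* Exact Wilcoxon enumeration is O(2^n); above n = 12 the normal
  approximation takes over.
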