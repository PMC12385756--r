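---
title: "Noise-robust recognition with covariance feature enhancement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-robust recognition with covariance feature enhancement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(narmnet)
```

# The problem

Fine-grained food-image recognition must separate classes that look alike
(inter-class similarity) while tolerating wide variation within one class
(intra-class variability). Real photographs add a further obstacle: sensor
noise and poor lighting perturb exactly the subtle texture statistics that
distinguish similar dishes. `narmnet` implements a training framework that
attacks both problems jointly: second-order (covariance) pooling with an
eigenvalue enhancement that protects small-eigenvalue texture directions,
an auxiliary image-restoration task that pushes the shared backbone towards
noise-invariant features, a staged multi-stage fusion curriculum, and a
temperature-scheduled distillation recipe that transfers the resulting
accuracy into a plain, cheap backbone.

Everything runs at desk scale on one CPU: the package ships a procedural
generator of small labelled texture images, and all network operators
(convolution, batch normalization, pixel-shuffle upsampling, the
covariance pooling itself) are implemented with hand-derived backward
passes that the test-suite verifies against central finite differences.

# Eigenvalue-enhanced global covariance pooling (EGCP)

Given a tapped feature map `x` with D channels over N = H x W positions,
EGCP proceeds in four steps.

**Normalization.** Each channel is standardised over its spatial positions,
`(x_d - mu_d) / sqrt(sigma2_d + eps)`, with population (1/N) variances.
This balances the channel distributions before any second-order statistic
is formed, and the per-channel weights `w_d = 1 / (sigma2_d + eps)` are
kept: a channel with large variance — the signature of a noise-dominated
channel — receives a small weight.

**Weighted covariance.** The package forms
`P = (1/N) (W^{1/2} Xt)(W^{1/2} Xt)^T`, where `Xt` is the centred
normalized D x N feature matrix and `W = diag(w_d)`. `P` is the channel
covariance with a diagonal channel reweighting; combining the
normalization and the sqrt-weight, row d of the weighted matrix is simply
`(x_d - mu_d) / (sigma2_d + eps)`, which is how the differentiable
implementation computes it. The diagonal-reweighting form is the one
construction that yields a genuine D x D second-order statistic over
channels while preserving the monotone variance-to-weight relation.

**Regularisation and enhancement.** `P_reg = P + eps I` is
eigendecomposed, eigenvalues are floored at `eps`, and enhanced by
`lambda_en = log(1 + lambda)`. The log is the heart of the method: its
secant slope `log(1 + l) / l` is strictly decreasing, so small eigenvalues
— the directions carrying subtle texture differences, and the first to be
drowned by noise — are amplified *relative to* the dominant ones.

**Dynamic scaling.** From `P_en = U diag(lambda_en) U^T` the package forms
the scaling matrix `S = U exp(-diag(lambda_en)) U^T`, the cross matrix
`Q = P_en^{1/2} S`, and the scalar `S_F = ||Q||_F`, for which the spectral
closed form `sqrt(sum lambda_en exp(-2 lambda_en))` — the Frobenius norm
expressed through the eigenvalues of `Q` — is computed as a cross-check on
every call. The final feature is
`A = (S_F + 1) P_en^{1/2}`, flattened row-major to a length-D^2 vector.
The matrix square root is taken in the eigenbasis — valid because the
enhanced spectrum is nonnegative — rather than by Newton–Schulz iteration;
at desk scale exact eigendecomposition is cheaper and more accurate.

Repeated eigenvalues make the eigenbasis non-unique, but every quantity
EGCP outputs is a spectral function of `P_reg`, hence basis-independent;
the tests assert conjugation equivariance instead of pinning a basis. The
backward pass uses the Loewner divided-difference form of the spectral
derivative, which degrades gracefully to `f'(lambda)` for (near-)repeated
eigenvalues. `eps` defaults to `1e-5`; it acts as the variance guard, the
covariance ridge, and the eigenvalue floor.

# The Noise Adaptive Recognition Module (NARM)

A NARM attaches to one backbone stage and has two branches fed by the same
tapped feature.

The **ARU** (recognition branch) is FTM -> EGCP -> SCM: a 1x1 convolution
to a bottleneck width (default D/2), BatchNorm and ReLU, a 3x3 convolution
to the EGCP width D; then EGCP; then the head, which treats the flattened
`A` as a D^2-channel 1x1 map: linear to D', BatchNorm, ReLU, linear to the
N class logits — the minimal convolution–BatchNorm–ReLU stack that ends in
an N-vector. The head consumes the EGCP output, not any FTM intermediate.

The **RTU** (restoration branch) recovers the clean image from the same
stage feature. The PRM chains x2 sub-pixel upsampling modules — each
`ReLU(Conv(PixelShuffle(x)))`, channels roughly halving per module — until
the stage resolution reaches the input resolution, then projects to 3
channels with a final 3x3 convolution without ReLU, so outputs are
unbounded during training and clamped to [0, 1] only at evaluation. The
number of modules is `log2(H'/H_stage)` per insertion stage — the
four-module chain quoted for the reference architecture is exactly the
28 -> 448 case. The LFS applies two 3x3 convolutions (3 -> D'' -> 3,
literally two convolutions with no intermediate activation, as specified)
to the noisy input image, and the restored image is the pixel-wise sum
`I_PRM + I_LFS`.

The restoration branch is initialised near the identity: the PRM output
projection starts close to zero and the LFS close to a pass-through, so
the initial restored image is approximately the noisy input. Training then
improves on the identity restorer instead of first un-learning a random
one — the standard residual formulation of learned denoising.

The joint loss is `L_NARM = alpha * L_rec + beta * L_mse` with softmax
cross-entropy `L_rec` and pixel MSE `L_mse` (computed on unclamped
restored images); the default weights (0.6, 0.4) keep classification
slightly dominant: a pure classification objective (beta = 0) leaves
noise-induced feature biases uncorrected, a pure restoration objective
(alpha = 0) starves the classifier of semantic supervision, and a
classification-heavy blend performs best in loss-weight sweeps.

# Weighted multi-granularity fusion (WMF)

S NARMs sit on the last S backbone stages (three in the reference
configuration, two on the tiny desk-scale backbone). Each training batch
runs S + 1 backward passes in a fixed order: one per NARM loss, shallow to
deep, then one for the classification loss of the fused head, which
consumes `x* = sum_i beta_i x_i'` — each tapped feature projected by a 1x1
convolution to a common width and average-resampled to the deepest tapped
grid. The default weights (0.2, 0.35, 0.45) favour deeper stages and sum
to one. Because the staged procedure never states an explicit optimizer
step, the package accumulates gradients across all S + 1 backward passes
and applies a single SGD update per batch: per-pass immediate updates
would make the result depend on the order of the losses within a batch.
NARM gradients do flow into the backbone stages beneath their tap — the
stagewise curriculum supervises shallow layers first, it does not freeze
them — and all NARMs share one forward pass of the backbone. The fusion
head is its own ARU (projection convolutions + FTM + EGCP + SCM), not a
shared per-stage head.

Optimisation is SGD with momentum 0.9 under a cosine annealing schedule
`lr(t) = floor + (lr0 - floor)/2 (1 + cos(pi t / horizon))` from
`lr0 = 0.002` at full scale; the desk-scale experiments below use a larger
`lr0 = 0.02` appropriate to their tiny batch count.

# Progressive temperature-aware feature distillation (PTAFD)

The trained WMF teacher is distilled into a plain backbone + global
average pooling + linear student. Phase 1 minimises
`alpha * L_distillation + (1 - alpha) * L_student` (default `alpha = 0.5`)
plus an optional per-stage feature-alignment term; phase 2 fine-tunes with
plain cross-entropy, teacher detached. `L_distillation` is the soft-label
cross-entropy with teacher *and* student logits softened at the same
temperature — the conventional choice — and deliberately carries no
`T^2` gradient-compensation factor: the total is exactly
`alpha * L_distill + (1 - alpha) * L_student`, a documented deviation from
common distillation practice.
`L_student` is the hard-label cross-entropy at T = 1.

The temperature schedule rises linearly from 0.5 to 2.0 across phase 1:
sharp teacher labels early (T < 1 concentrates the student on confident
predictions), smoothed labels late (T = 2 exposes inter-class structure).
Both directions have a rationale (sharp-first concentrates on confident
labels; smooth-first aligns coarse structure), so the falling variant
stays selectable via `T_start > T_end`; the rising schedule is the
default. The feature-alignment term carries no temperature of its own —
its progressiveness is carried by the phase split. Phase lengths default
to roughly 80% / 20% of the epoch budget.

Feature alignment itself is the mean over stages of the MSE between globally
L2-normalized features, with a learned 1x1 projection when the widths
differ; the normalization makes the distance scale-invariant, so a student
that reproduces the teacher's feature directions at a different gain pays
nothing. The teacher's fused head provides the soft labels (not an average
of per-stage heads).

# The synthetic data generator

Real food photographs are neither shipped nor downloaded. The generator
emulates the two properties the method needs from its data: classes that
overlap in colour but differ in texture statistics, and intra-class
variation from per-image jitter of scale, rotation and brightness.
Consecutive classes share a texture family (stripes, blobs, granules) and
differ only in its scale (frequency / blob radius / granule smoothness),
so even a 3-class set is fine-grained. Texture contrast is calibrated
(amplitude 0.08 on the [0, 1] pixel scale) so that the datasets satisfy
both preconditions of a noise-robustness study: a small clean-trained CNN
separates the classes essentially perfectly on clean test images, while
additive Gaussian pixel noise at sigma = 0.2 measurably degrades it —
without that degradation the robustness comparisons would be vacuous.
What the generator does *not* emulate: backgrounds and occlusion, class
imbalance, illumination fields, real camera noise (which is neither
Gaussian nor signal-independent), or any semantic content. Conclusions
from passing tests are therefore about the training mechanics, not about
photographs.

Noise injection adds independent `N(0, sigma^2)` per pixel per channel on
the [0, 1] scale (before any channel standardization — sigma = 0.1 has its
intended meaning only there), clips to [0, 1] by default (disabled inside
the moment tests), is applied to training inputs only (evaluation splits
stay clean unless a robustness sweep asks otherwise), and is drawn from a
fixed seed, so a training set's noise field is reproducible. The sweep
grid is sigma in {0.01, 0.05, 0.10, 0.15, 0.20} with 0.10 the default
training level. The full-scale preprocessing pipeline (bilinear resize to
550, center crop to 448, ImageNet-statistics standardization with the
conventional constants 0.485/0.456/0.406 and 0.229/0.224/0.225) is
implemented and tested, and the toy pipeline preserves its 448/550 crop
ratio (80 -> 64) where used.

# Numerical choices and degenerate inputs

* `eps = 1e-5` throughout EGCP; a single spatial position yields the zero
  covariance (centering annihilates the sample) and the pipeline still
  runs, as the all-zero hand-trace test checks.
* Eigen-derivative divided differences switch to the analytic derivative
  when `|lambda_i - lambda_j| < 1e-9 max(1, |lambda_i|)`.
* Score ties in rankings break towards the lowest class index, making
  evaluation platform-independent; classes with no predicted and no true
  instances get F1 = 0 with a warning; run aggregation uses the sample
  (n - 1) standard deviation.
* Batch normalization uses batch statistics in training and running
  averages (momentum 0.1) at inference; all forward passes are
  deterministic under a fixed seed, with stochasticity confined to data
  order, initialisation and noise draws.
* The flattening of `A` is row-major, fixed for checkpoint compatibility.

# Desk-scale study conditions

The test-suite and the acceptance script run the following problem sizes,
chosen once as the package's desk-scale study conditions:

* **End-to-end teacher training**: 3 classes x 50 images at 64 x 64
  (60/10/30 split), tiny 3-stage backbone (8/16/32 channels) with NARMs on
  the last two stages, EGCP width D = 16, batch 15, `lr0 = 0.02`,
  sigma = 0.10 training noise, at most 30 epochs with early stop once the
  training split is fit and the restoration branch beats the identity
  baseline on held-out noisy images.
* **Robustness comparison (restoration branch on vs off)**: 3 classes x 30
  images at 32 x 32, 14 epochs, three seeds, evaluated at test-time
  sigma in {0, 0.05, 0.10, 0.15, 0.20}.
* **Distillation comparison**: the same 32 x 32 data; one teacher; five
  seeds of distilled student (6 + 2 epochs) against an identically
  initialised, identically scheduled plain-CE baseline.

These sizes are deliberately small: stochastic trend-level checks
(robustness curves, distillation gains) are asserted as means over seeds,
mirroring the five-seed mean +/- SD reporting convention of the full-scale
protocol.

# Known limitations

* The toy backbone is a plain conv–BN–ReLU–pool stack; no residual
  connections, so conclusions about very deep backbones do not transfer.
* The restoration branch is evaluated by MSE only; perceptual quality
  metrics are out of scope.
* Distillation baselines beyond the package's own loss (relational,
  correlation-based, attention-based variants) are not implemented; the
  loss interface is the extension point.
* The CLI trains on in-memory datasets; nothing is streamed, so dataset
  size is bounded by memory — intentional at desk scale.
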