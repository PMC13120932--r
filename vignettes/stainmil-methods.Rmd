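---
title: "Stain-robust structured aggregation for histopathology classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-robust structured aggregation for histopathology classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainmil)
```

## The problem

Binary classification of H&E-stained oral histopathology images (Normal vs.
oral squamous cell carcinoma, OSCC) is complicated by two properties of real
slide collections. First, staining chemistry, scanner optics and laboratory
protocol vary between sites, so color is a strong but diagnostically
irrelevant signal: a classifier trained on one site's palette can learn a
color *shortcut* that collapses under domain shift. Second, the diagnostic
evidence is spatially local and structured — nuclear morphology, boundary
continuity, tissue architecture — so image-level prediction is naturally a
multiple-instance problem over a grid of patches with meaningful spatial
relations between them.

`stainmil` implements a classification framework that addresses both issues
*in feature space*, after a backbone network, rather than by input-side stain
normalization: a morphology-dominant encoder with staining-bias suppression,
followed by a spatially structured graph-transformer aggregation head.

## Model

### Token backbone

An input image $x \in \mathbb{R}^{H \times W \times 3}$ is mapped to a
token-level feature matrix $F \in \mathbb{R}^{N \times C}$ on a 2-D grid of
$G_h \times G_w = N$ spatial locations. The backbone is a pluggable contract
(`extract_tokens()` plus a backbone handle): any hierarchical feature
extractor producing a final-stage token grid can be wrapped with
`backbone_adapter()` (e.g. a Swin-style transformer with patch size 4 and
window 7, at 224 × 224 input). For desk-scale training and testing the
package provides `backbone_mini()`, a small *trainable* two-stage
patch-embedding network (a 4 × 4 linear patch embedding with ReLU followed
by a 2 × 2 patch merge; total stride 8). Two stages of non-overlapping patch
projections keep the hand-derived backpropagation exact and fast on one CPU;
spatial context is deliberately left to the morphology branch and the head,
which is where this architecture locates it anyway. Coordinates are 0-based,
row-major, in token-grid units throughout.

Channel normalization defaults to mean 0.5 / sd 0.5 per channel (mapping
pixels to $[-1, 1]$); ImageNet constants are appropriate when wrapping a
pretrained adapter.

### Morphology-dominant encoding with staining-bias suppression (SDA)

Backbone tokens are factorized into two components of the same shape:

* a **stain-related component** $F_s = \mathrm{MLP}_s(F)$, a token-local
  feed-forward map (one hidden layer of width $C$, ReLU). Because it mixes
  no spatial context, it can express color distribution and staining
  intensity but not structure. Token locality is verified in the tests by
  finite differences.
* a **morphology-dominant component**
  $F_m = F + \mathrm{DWConv}(\mathrm{WAttn}(F))$, a residual branch in which
  single-head scaled dot-product attention inside non-overlapping windows on
  the token grid captures short-range structure, and a 3 × 3 depthwise
  convolution injects local texture and boundary sensitivity. With zeroed
  branch parameters $F_m \equiv F$ exactly.

A per-token gate computed from the *raw* backbone features,
$\alpha = \sigma(F w_\alpha + b_\alpha) \in (0,1)^{N \times 1}$, fuses the
components by a rowwise convex combination broadcast across channels:

$$\tilde F = \alpha \odot F_m + (1 - \alpha) \odot F_s.$$

The decomposition is architectural only: no auxiliary loss forces $F_s$ to
capture stain variation, exactly as in the underlying design, and the
package makes no identifiability claim for it. Whether the mechanism
*behaves* as intended is probed empirically by the shortcut experiment
(below), not assumed.

Choices on points the design leaves open: window attention is unshifted;
windows on grids not divisible by the window size are formed by
edge-replication padding (each padded cell reads its clamped source token,
gradients scatter-add back); a grid smaller than one window falls back to a
single global window with a logged message. The gate weights are
zero-initialized so training starts from the neutral $\alpha = 1/2$.

### Spatial transformer classifier head

Tokens become graph nodes. With grid coordinate $p_i$, a positional encoding
(fixed 2-D sinusoidal by default, learnable table optional) is projected to
the node dimension, $e_i = \mathrm{PE}(p_i) W_p \in \mathbb{R}^d$, and node
states are initialized as $h_i^{(0)} = \tilde f_i W_f + e_i$.

Topology is dual: with Euclidean grid distance $d_{ij}$ and radius $r$
(default 1.5 token units, the 8-neighborhood including diagonals),
$A^{adj}_{ij} = \mathbb{1}[d_{ij} \le r]$ and $A^{non} = 1 - A^{adj}$. The
diagonal ($d_{ii} = 0$) stays in $A^{adj}$, per the literal indicator.
Content-based scores $S = (h^{(0)} W_q)(h^{(0)} W_k)^\top / \sqrt{d}$ are
softmax-normalized *within* each support (max-subtraction per row support for
stability; rows with empty support become all-zero rows rather than NaN —
the only finite, order-independent convention), and fused by a learnable
coefficient $\lambda = \sigma(\theta) \in [0,1]$:

$$\hat A = \lambda \hat A^{adj} + (1 - \lambda) \hat A^{non}.$$

Two readings of the published equations required a decision and both are
recorded here. (1) The score divisor is read as $\sqrt{d}$, the standard
scaled-attention idiom for a "projection dimension". (2) $\hat A$ is
computed **once** from $h^{(0)}$ and reused at every layer; only the inner
attention softmax is per-layer — the literal reading of the layer equations.
Each of the $L$ layers (default 2) computes

$$h^{(\ell+\frac12)} = \big(\hat A \odot \mathrm{softmax}(Q^\ell
{K^\ell}^\top / \sqrt d\,)\big)\, h^{(\ell)} W_v^\ell, \qquad
h^{(\ell+1)} = \mathrm{ReLU}\big(\hat A\, h^{(\ell+\frac12)} W_g^\ell\big) +
h^{(\ell)},$$

i.e. the elementwise product of the fixed structure matrix with a fresh
attention, *without* renormalization — the literal form. Because the product
of two row-stochastic-ish matrices is generally not row-stochastic, a config
flag `renormalize_attention` (default off) restores row sums of one for
experimentation; fidelity first, ergonomics second.

Aggregation is a gated-attention MIL readout,
$a_i \propto \exp(u^\top \tanh(h_i^{(L)} W_a))$, $z = \sum_i a_i h_i^{(L)}$
(so $z$ lies in the convex hull of the node states), followed by a 2-class
softmax $\hat y = \mathrm{softmax}(z W_c + b_c)$.

Because every spatial structure is derived from the coordinates rather than
the row order, permuting tokens together with their coordinates leaves the
prediction unchanged; the test suite asserts this, along with full
scalar-loop equivalence of the whole head for all $N \le 16$.

## Training protocol

* **Splitting**: stratified 7:1:2 with the per-class rounding rule
  `round(0.7 n)` / `round(0.1 n)` / remainder. This rule reproduces all
  eight published per-class counts of the two benchmark datasets
  (203/29/58, 654/93/187, 1051/150/301, 7132/1019/2037) and is therefore
  fixed.
* **Imbalance handling**: class-weighted cross-entropy with balanced inverse
  frequencies $w_c = n_{train} / (2 n_c)$, plus class-balanced batch
  composition (each epoch resamples the minority class so batches are
  approximately class-balanced). The published protocol names "stratified
  sampling" without defining it; batch balancing is this package's reading
  and is configurable off.
* **Optimization**: AdamW (decoupled weight decay $10^{-2}$), cosine-annealed
  learning rate from the initial value, global gradient-norm clipping at 1.0,
  fixed seed. All gradients are hand-derived matrix calculus; the tests
  compare every parameter against central finite differences at $10^{-4}$
  relative tolerance.
* **Checkpoint selection**: the epoch maximizing validation F1 (the
  published recipe says only "validation performance"; F1 suits the
  imbalanced setting and is configurable to accuracy).
* Mixed precision is not implemented: R computes in double precision, and at
  desk scale determinism is worth more than memory bandwidth.

The reference configuration mirrors the published recipe (224 × 224 input,
batch 32, AdamW, lr $10^{-4}$, weight decay $10^{-2}$, cosine schedule,
clipping 1.0, seed 42); desk-scale runs shorten the schedule and raise the
learning rate as described below.

## The synthetic stain-shift generator

The generator exists so the central claim — feature-space suppression of
stain bias — is testable without any external data. It emulates exactly the
two axes the model cares about:

* **Morphology carries the label.** Irregular nuclear blobs are placed on a
  smooth textured background; class 1 ("OSCC-like") draws more nuclei
  (18–28 vs. 6–12) with higher boundary irregularity (0.45 vs. 0.15,
  radial harmonic perturbation). The blob count is recorded per image, the
  label is a deterministic threshold of it, and the two count ranges are
  disjoint — so a color-blind classifier can in principle be perfect, which
  is what makes the stain-suppression claim falsifiable here.
* **Stain style is a domain.** Each domain applies an affine transform in
  optical-density space, $I' = \exp(-( g \odot (-\log I) + o))$, mimicking
  Beer–Lambert stain physics; the two default domains tilt the palette
  toward eosin (pink) or hematoxylin (purple). Styles invert exactly, and
  the identity style is a bit-for-bit no-op.
* **The confound dial.** $\rho \in [-1, 1]$ sets the label–domain
  correlation within a split by exact counts: $\rho = 0$ decorrelates
  (mutual information zero by construction up to count rounding), $\rho = 1$
  assigns each class its own stain domain.

Everything is deterministic in (spec, seed), down to the PNG bytes; in-memory
pixels are quantized to 8 bits so the file and in-memory paths agree.

What the generator does **not** emulate: real nuclear chromatin texture,
tissue-architecture context (glands, invasion fronts), scanner noise,
magnification effects, or label noise. Passing the shortcut experiment on
these images therefore demonstrates the *mechanism* — that the architecture
can prefer morphology over a color shortcut under a controlled confound —
not clinical-grade robustness on real cohorts.

## The shortcut experiment

`shortcut_experiment()` trains two arms on identical data per seed: the full
model, and an ablation with the SDA module replaced by the identity
(backbone + head only). Training and validation data carry a strong
label–stain confound ($\rho = 0.9$: stain style predicts the label 95% of
the time); the test split is regenerated at $\rho = 0$, where color is
useless. The comparison is direction-only — the full model's median shifted-
test accuracy across seeds against the ablation's — mirroring how the
module's contribution is reported in the underlying ablation study. A null
control repeats both arms at $\rho_{train} = 0$, where the arms should be
statistically indistinguishable (median gap within the across-seed spread).

Desk-scale study conditions, chosen once for a single CPU: 400 images
(120/280 per class, roughly the published class imbalance), 64 × 64 px,
mini-backbone with $C = 24$, head dimension $d = 32$, $L = 2$, SDA window 4
(dividing the 8 × 8 token grid), 20 epochs, batch 32, initial lr
$2 \times 10^{-3}$ (scaled up from the published $10^{-4}$ because the
schedule is 10× shorter; calibrated only against training-loss convergence),
5 seeds. The numbers this experiment produces are computed by
`scripts/acceptance.R` and by the acceptance tests; this vignette
deliberately states none of them.

## Evaluation metrics

Accuracy, precision, recall and F1 follow the standard confusion-matrix
definitions with OSCC as the positive class, reported in percent at two
decimals. AUC is computed as the tie-aware Mann–Whitney rank statistic,
which equals the trapezoidal integral of the empirical ROC curve; the tests
cross-check it against both an $O(n^2)$ pairwise oracle and pROC. Degenerate
denominators (e.g. no positive predictions) return an explicit `NA` marker
with a message rather than a silent 0, so evaluation bugs surface.
`worked_examples()` reproduces the published benchmark metric values from
the published confusion counts and flags the one printed value that is
inconsistent with its own counts (the ORCHID full-model recall; the counts
give 78.40 while the table prints 78.04 — almost certainly a transposition).

## Numerical and degenerate-input conventions

* Masked softmax rows with empty support are exact zeros; a single-token bag
  therefore has $\hat A = \lambda \cdot 1$ and everything downstream stays
  finite.
* $\lambda$ is a global scalar (the structure fusion appears once, before
  the layer stack), parameterized through a sigmoid and initialized at 0.5.
* Window attention ties are irrelevant (softmax), and `max.col`-based
  row maxima use first-tie-wins purely for stabilization, which cancels.
* Non-finite losses abort training with a diagnostic rather than continuing.
* Images must be divisible by the backbone stride; there is no silent crop.

## Known limitations

* The stain/morphology factorization has no identifiability guarantee; the
  gate can in principle route color information through either branch. The
  package measures the behavioral consequence instead of asserting the
  mechanism.
* The graph structure is dense ($N \times N$); whole-slide-scale token
  counts would need sparse or hierarchical approximations that are out of
  scope here.
* The mini backbone is intentionally small; results at desk scale
  characterize the aggregation and suppression modules, not
  state-of-the-art representation learning.
* JPEG decoding is not wired in (the generator and fixtures use PNG
  throughout); wrap an external decoder into an array and call
  `resize_and_normalize()` directly if needed.
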