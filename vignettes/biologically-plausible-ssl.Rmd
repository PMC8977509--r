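---
title: "Biologically plausible self-supervised training: models, rules and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biologically plausible self-supervised training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plausnet)
```

## The problem

Backpropagation is a poor model of cortical learning for two well-known
reasons: it reuses the feedforward synaptic weights, transposed, to carry
error signals backwards (the *weight transport* or symmetric-weight problem),
and it relies on dense supervision. plausnet implements a family of training
mechanisms that relax both constraints for small convolutional encoders:

* **Contrastive self-supervision with a hinge loss.** Two independently
  deformed views of an image (crop, flip, photometric jitter) form a positive
  pair; a handful of *temporally close* other images form negatives. The loss
  is a sum of margin hinges on L1 distances between embeddings,
  \deqn{L = \sum_s [\|x_s^A - x_s^B\|_1 - m_1]_+ + \sum_{t \in N_s} [m_2 - \|x_s^A - x_t^B\|_1]_+.}
  Its gradient with respect to any embedding coordinate is an integer sum of
  sign terms gated by two batch-level indicators, so the top-layer update is
  a plain Hebbian product of a pre-synaptic activity and a locally computable
  post-synaptic error — no normalization, inner products or divisions, unlike
  the temperature-scaled cosine cross-entropy (also provided, as
  `simclr_loss()`, for comparison).
* **Gradient blocking.** By default the anchor branch contributes nothing to
  the update: the anchor embedding is treated as a short-term-memory trace
  that is only *read* when the second view or a negative arrives. This is the
  temporally most local variant; `hinge_config(block_gradient = FALSE)`
  restores the full gradient.
* **Interchangeable credit assignment.** Error propagation through the
  encoder can use BP (transposed weights), RF (fixed random feedback blocks),
  or URF (random feedback blocks receiving the transposed increments of the
  forward weights); see `feedback_state()`. Layer-wise training (GLL/RLL)
  confines any of these to a single hidden layer. DTP replaces error
  propagation altogether with per-layer targets carried by learned inverses.

## Network model

`build_network()` assembles a stack of `layer_spec()`s: convolutions
(3x3, stride 1, "same" zero padding so only pooling downsamples), 2x2
max/average pooling, flatten, and linear layers, with elementwise `hardtanh`
(clamped to [-1, 1]) or `tanh` nonlinearities. Every trainable layer computes
`h = W x` with no bias, and the top (projection) layer applies no
nonlinearity. Two reference encoders are shipped: a 5-conv/3-maxpool network
for 32x32 RGB inputs with a 64-unit linear head (`config_cifar_encoder()`),
and a 3-conv/3-maxpool `tanh` network for 28x28 grayscale inputs
(`config_mnist_encoder()`). A VGG6-style config is included as an explicitly
approximate extra (`config_vgg6_approx()`); the composition it imitates is
not fully specified anywhere we implement from, so nothing depends on it.

Numerical conventions that the tests pin down:

* weights initialized uniformly in ±1/sqrt(fan-in); feedback blocks `B`
  drawn independently from the same scheme, stored in the transposed
  orientation of the layer's linearized map;
* max-pool ties broken by the first index in row-major window order, and the
  winning index recorded for deterministic error routing;
* images are channel-first arrays in [0, 1]; embeddings are `(dim, n)`
  matrices with one column per sample.

## Deformations

All geometric deformations (random resized crop, horizontal flip, affine
rotation/shear/translation) are realized through one inverse-map bilinear
sampler with zero fill, so the identity transform and integer translations
are exact — properties the test suite checks against index-shift oracles.
Photometric jitter (brightness, contrast, and for RGB saturation/hue) is
plain channel arithmetic clamped to [0, 1]. Defaults follow the common
contrastive-pretraining convention (area scale in [0.2, 1], flip probability
0.5, jitter strengths 0.4/0.4/0.4/0.1, grayscale probability 0.1); the
grayscale presets used in the studies disable the color-only components.
"Temporal closeness" of negatives is realized as cyclic batch order:
`select_negatives(n, T, s)` returns the `T` indices following anchor `s`,
from the deformed B branch. The B-branch convention matches the loss's
notation; whether negatives should be drawn before or after deformation is
not fully determined by the source material, and the deformed-branch reading
keeps every compared quantity an embedding of an actually presented view.

## Feedback rules

`backward_errors()` implements
\deqn{\delta_l = \sigma'(h_l) \odot (M^\top \delta_{l+1}),}
with `M` the forward weight under BP and the feedback block under RF/URF.
Pooling layers route errors to the recorded argmax (max) or spread them
uniformly (average); this routing is shared by all rules, since the rules
differ only in how they traverse trainable maps. URF applies the transposed
forward increment to `B` at optimizer time, which makes the URF-equals-BP
identity under symmetric initialization exact to the last bit — one of the
package's standing self-checks (`cmd_selftest()`).

The reference update is plain SGD, matching the update equations; an
Adam-style preset is the default in the trainers because the experiments the
package models used Adam. The mechanism-comparison study uses the full-scale
encoder learning rate (1e-4) uniformly; the BP-only pretraining runs in the
representation study use 1e-3, chosen once so that short desk-scale runs
move the loss far from initialization.

## Difference target propagation

`dtp_network()` groups the encoder into stages `f_l` (conv + following
pooling/activation; top stage flatten + linear) and builds backward stages
`g_l`, `l = 2..L`: strided deconvolutions for conv stages — realized as the
adjoint of a strided convolution whose kernel/stride/padding are solved per
stage so that `g_l`'s output shape equals `f_l`'s input shape exactly — and
a linear map for the top stage. Each `dtp_step()`:

1. forwards both view branches;
2. takes one SGD step per inverse on
   `L_l^inv = mean_batch ||g_l(f_l(x_{l-1})) - x_{l-1}||^2` (clean
   activations, no noise injection, per the single-step variant);
3. sets the top target `xhat_L = x_L - eta_L dL/dx_L` from the hinge error
   signals (blocking honored) and propagates difference-corrected targets
   `xhat_{l-1} = x_{l-1} - g_l(x_l) + g_l(xhat_l)`;
4. updates every `f_l` on its local loss (top stage on the global loss),
   using only `x_{l-1}` and `xhat_l` — never a transposed forward weight of
   the stage above (asserted in the tests by corrupting upper weights and
   checking the update is unchanged).

Numerical choices: the difference correction is computed as
`g_l(xhat_l - x_l)` — identical for the linear `g_l` used here — so a zero
top gradient leaves targets bit-identical to activations and all lower local
losses exactly zero. Local losses are averaged over the batch so step sizes
do not scale with the desk-scale batch; `eta_L` defaults to the forward
learning rate, since no value is prescribed for it. The single-step
algorithm specifies SGD for both parameter groups while the full-scale
experiments it abstracts used Adam for the encoder; the optimizer is
therefore exposed per group, with SGD for the inverses (learning rate 0.001)
and the Adam preset for forward stages as the trainer default.

## Layer-wise training

Each trainable conv stage gets an auxiliary head (flatten + linear into the
64-dimensional embedding space — the head architecture is not prescribed, so
it mirrors the final projection head). GLL trains stages strictly bottom-up,
each for a fixed number of steps; RLL draws the trained stage uniformly per
batch and forwards through preceding stages at their current values, so all
layers train simultaneously without sequencing. In both modes exactly one
stage and its head change per step (checksum-asserted), and the single
hidden layer is trained with BP, RF or URF — the shallow regime where random
feedback is known to work. Heads are discarded at evaluation time and
replaced by a linear classifier.

## Evaluation protocols

*Linear evaluation*: freeze the encoder, drop the projection head, train a
multinomial linear classifier (with bias; Adam, learning rate 0.001) on the
flattened last-conv-block features, report held-out exact-match accuracy.
*Robustness*: train the probe on undeformed data and test on a deformed copy
of the test set (default affine preset: rotation ±25°, translation ±15%,
shear ±10° — plausible printed-digit-style perturbations, shipped as
documented presets since no exact values are prescribed), paired with a
supervised baseline of the same architecture trained end-to-end on the same
labeled data. `margin_histogram()` plots the initial positive/negative L1
distance distributions and suggests margins from quantiles — the same
diagnostic that motivates the shipped presets `m1 = 1, m2 = 3` (32x32 RGB
scale) and `m1 = 1, m2 = 1.5` (28x28 grayscale scale).

## The synthetic fixture

`generate_synthetic()` renders four (up to eight) geometric shape families —
blobs, rings, crosses, diagonal stripes, bars, textures — at 28x28 with
nuisances in position (±20% of the side), scale (0.6–1.4), intensity
(0.4–1) and additive Gaussian pixel noise (sd 0.12). The nuisance
amplitudes are deliberately large: they give the probe tasks dynamic range
(a random-encoder probe does not saturate at 100%), mimic the
pose/lighting variability that view deformations are meant to bridge, and
keep class identity invariant under every deformation family by
construction. A disjoint-family variant (`generate_disjoint_pair()`)
realizes the pretrain-on-X/probe-on-Y transfer protocol.

What the fixture does *not* emulate: natural image statistics, clutter,
occlusion, or inter-class texture similarity. Passing the package's studies
on this fixture demonstrates that the mechanisms work — losses fall, learned
embeddings beat random ones, SSL embeddings transfer under held-out
deformations — not that full-scale benchmark accuracies would be reproduced.

## Desk-scale studies and problem sizes

`run_mechanism_comparison()` trains every trainer × rule combination
(E2E/GLL/RLL × BP/RF/URF, plus DTP) for 200 steps at batch size 16 on the
default fixture and reports the hinge loss on a fixed probe batch before and
after training. It uses the full-scale experiments' encoder learning rate
(Adam, 1e-4) for every combination: end-to-end random feedback, whose
misaligned lower-layer updates amplify under aggressive per-parameter step
normalization, is stable there, and all mechanisms remain comparable under
one shared preset. Layer-wise runs are scored through their trained top
auxiliary head — the objective those trainers actually optimize — while
end-to-end and DTP runs are scored through the projection head. `run_representation_study()` runs, per seed: 150 steps of
E2E contrastive pretraining, linear probes of the trained and a random
encoder, and a 150-step supervised baseline, then evaluates all three on an
affine-deformed test set. These problem sizes are the package's chosen
desk-scale conditions: large enough that every mechanism moves its loss far
from initialization and the orderings of interest are visible, small enough
that the full battery runs in minutes on one CPU core. `scripts/acceptance.R`
reruns both studies from scratch.

## Known limitations

* Pure-R execution: convolutions are im2col + BLAS; fine at 28x28–32x32
  desk scale, not meant for large images or hundreds of epochs.
* Weight sharing in convolutions (and the argmax bookkeeping of max-pool
  error routing) are themselves biologically questionable; they are kept
  because the mechanisms under study are the loss and the credit-assignment
  rules, not the layer types.
* The SimCLR-style loss is provided for comparison only; no
  negative-free objectives (predictor/stop-gradient or redundancy-reduction
  methods) are implemented.
* `hardtanh` bounds are fixed at [-1, 1]; `sgn(0) = 0`; hinge indicators are
  strict inequalities, so loss and gradient agree at margin boundaries.
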