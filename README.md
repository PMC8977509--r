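# plausnet

Biologically plausible training mechanisms for self-supervised learning
(SSL) in small convolutional networks, implemented in pure R.

Standard deep learning is a questionable model of cortical learning: it
needs labels, and backpropagation reuses the feedforward weights —
transposed — to carry errors backwards (the symmetric-weight problem).
plausnet implements and tests a family of mechanisms that relax both
constraints, for researchers studying credit assignment and
self-supervision at desk scale:

* **Contrastive hinge loss.** For a batch of paired deformed views
  (anchors `x_s^A`, positives `x_s^B`, negatives `x_t^B`, `t` in a small
  temporal window `N_s`):

  ```
  L = Σ_s [ ||x_s^A − x_s^B||₁ − m₁ ]₊  +  Σ_s Σ_{t∈N_s} [ m₂ − ||x_s^A − x_t^B||₁ ]₊
  ```

  Its error signal per coordinate is a sum of sign terms gated by two
  batch indicators, so the top layer learns with a pure Hebbian update —
  no normalization, inner products or divisions. With *gradient blocking*
  (default) the anchor embedding acts as a read-only short-term-memory
  trace. The temperature-scaled cosine cross-entropy (`simclr_loss()`) is
  included as the conventional baseline.
* **Credit assignment**: backpropagation (BP), fixed random feedback
  (RF), updated random feedback (URF, feedback receives the transposed
  forward increments), single-step difference target propagation (DTP)
  with pooling forward stages and learned strided-deconvolution inverses,
  and greedy / randomized layer-wise training (GLL / RLL) with auxiliary
  heads, where any of BP/RF/URF acts over a single hidden layer.
* **Protocols**: linear-probe evaluation of frozen encoders,
  deformation-robustness evaluation against a paired supervised baseline,
  margin diagnostics, and a synthetic labeled-image generator so that
  everything runs with no downloads.

## Worked example

```r
library(plausnet)

ds  <- generate_synthetic(synthetic_spec(images_per_class = 120, seed = 1))
net <- build_network(config_mnist_encoder(), seed = 1)
dc  <- deformation_config(crop_scale_range = c(0.5, 1), flip_prob = 0.5,
                          jitter_strengths = c(0.4, 0.4, 0, 0),
                          grayscale_prob = 0)

fit <- train_e2e(net, ds$train$images, steps = 120, batch_size = 16,
                 deform_cfg = dc, loss_cfg = hinge_config_mnist(),
                 fb = feedback_state("BP", "adam", 1e-3), seed = 1)
tail(fit$history[, c("step", "loss")], 3)
#> # A tibble: 3 × 2
#>    step  loss
#>   <int> <dbl>
#> 1   118  13.1
#> 2   119  14.1
#> 3   120  14.2

rep <- linear_evaluation(fit$net, ds$train, ds$test, epochs = 25, seed = 1)
rep$probe_accuracy
#> [1] 0.9270833
linear_evaluation(build_network(config_mnist_encoder(), 99),
                  ds$train, ds$test, epochs = 25, seed = 1)$probe_accuracy
#> [1] 0.84375
```

The per-step `loss` is the summed contrastive hinge loss of the training
batch (it falls from ~48 at the first step to the low teens here). The
probe accuracy is a linear classifier on the frozen, head-stripped
encoder features; the SSL-trained encoder beats the random encoder of the
same architecture, which is the package's desk-scale analogue of the
trained-vs-random-encoder comparison.

Other entry points: `gll_train()` / `rll_train()` (layer-wise),
`dtp_network()` + `dtp_train()` (target propagation),
`robustness_evaluation()` (deformed-test-set protocol with a supervised
baseline), `margin_histogram()` (choose `m1`/`m2` on new data),
`cmd_selftest()` (gradient-oracle and identity checks). A thin CLI lives
in `inst/cli/plausnet` (`pretrain`, `evaluate`, `robustness`,
`generate-data`, `selftest`) with YAML run configs.

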