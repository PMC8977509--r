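# BP / RF / URF error propagation and parameter updates.

test_that("RF reduces to BP when feedback equals the forward transpose", {
  net <- set_symmetric_feedback(build_network(tiny_config(), seed = 3))
  X <- random_batch(c(1, 8, 8), 4, seed = 4)
  tr <- forward(net, X)
  td <- withr::with_seed(5, matrix(rnorm(10 * 4), 10, 4))
  bp <- backward_errors(net, tr, td, feedback_state("BP"))
  rf <- backward_errors(net, tr, td, feedback_state("RF"))
  for (l in seq_along(bp$grads)) {
    if (is.null(bp$grads[[l]])) next
    expect_equal(rf$grads[[l]], bp$grads[[l]], tolerance = 1e-12)
    expect_equal(rf$deltas[[l]], bp$deltas[[l]], tolerance = 1e-12)
  }
})

test_that("saturated units stop all error flow below them", {
  cfg <- network_config(c(1, 4, 4), list(
    layer_spec("flatten"),
    layer_spec("linear", channels = 8, activation = "hardtanh"),
    layer_spec("linear", channels = 3)), name = "sat")
  net <- build_network(cfg, seed = 6)
  net$layers[[2]]$W <- net$layers[[2]]$W * 0 + 10    # drive h far out of [-1,1]
  X <- random_batch(c(1, 4, 4), 3, seed = 7) + 0.5
  tr <- forward(net, X)
  bw <- backward_errors(net, tr, matrix(1, 3, 3), feedback_state("BP"))
  expect_true(all(bw$deltas[[2]] == 0))
  expect_true(all(bw$grads[[2]] == 0))
})

test_that("two-layer error signals match the hand-unrolled chain rule", {
  cfg <- mlp_config(hidden = 5, out = 3, act = "tanh")
  net <- build_network(cfg, seed = 8)
  X <- random_batch(c(1, 4, 4), 2, seed = 9)
  tr <- forward(net, X)
  td <- withr::with_seed(10, matrix(rnorm(3 * 2), 3, 2))
  bw <- backward_errors(net, tr, td, feedback_state("BP"))
  W2 <- net$layers[[2]]$W; W3 <- net$layers[[3]]$W
  X0 <- matrix(X, 16, 2)
  h1 <- W2 %*% X0
  # straight-line transcription: delta_l = sigma'(h_l) (W_{l+1}^T delta_{l+1})
  d2 <- (1 - tanh(h1)^2) * (t(W3) %*% td)
  expect_equal(bw$deltas[[2]], d2, tolerance = 1e-12)
  expect_equal(bw$grads[[3]], td %*% t(tanh(h1)), tolerance = 1e-12)
  expect_equal(bw$grads[[2]], d2 %*% t(X0), tolerance = 1e-12)
})

test_that("BP gradients through conv and pooling match central differences", {
  net <- build_network(tiny_config(channels = c(2L, 3L), embedding = 4L), seed = 11)
  X <- random_batch(c(1, 8, 8), 2, seed = 12)
  target <- withr::with_seed(13, matrix(rnorm(4 * 2), 4, 2))
  lossf <- function(nn) {
    tr <- forward(nn, X)
    sum((tr$x[[nn$L]] - target)^2) / 2
  }
  tr <- forward(net, X)
  bw <- backward_errors(net, tr, tr$x[[net$L]] - target, feedback_state("BP"))
  h <- 1e-6
  for (l in c(1, 3, 6)) {
    g <- bw$grads[[l]]
    idx <- withr::with_seed(l, sample(length(g), min(12, length(g))))
    for (i in idx) {
      np <- net; np$layers[[l]]$W[i] <- np$layers[[l]]$W[i] + h
      nm <- net; nm$layers[[l]]$W[i] <- nm$layers[[l]]$W[i] - h
      expect_equal(g[i], (lossf(np) - lossf(nm)) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("zero deltas leave the network unchanged; URF mirrors updates into B", {
  net <- build_network(mlp_config(), seed = 14)
  zero <- list(NULL, matrix(0, 12, 16), matrix(0, 6, 12))
  st <- apply_updates(net, zero, feedback_state("BP", "sgd", 0.1))
  expect_identical(lapply(st$net$layers, `[[`, "W"), lapply(net$layers, `[[`, "W"))

  g <- list(NULL, matrix(1, 12, 16), matrix(2, 6, 12))
  st2 <- apply_updates(net, g, feedback_state("URF", "sgd", 0.1))
  expect_equal(st2$net$layers[[2]]$W, net$layers[[2]]$W - 0.1 * g[[2]])
  expect_equal(st2$net$layers[[2]]$B, net$layers[[2]]$B - 0.1 * t(g[[2]]))
  # RF leaves feedback frozen
  st3 <- apply_updates(net, g, feedback_state("RF", "sgd", 0.1))
  expect_identical(st3$net$layers[[2]]$B, net$layers[[2]]$B)
})

test_that("URF with symmetric initialization tracks BP exactly over many steps", {
  expect_lt(plausnet:::urf_bp_divergence(seed = 15, steps = 40), 1e-12)
})

test_that("single-step BP on a one-hidden-layer net equals a numeric-gradient step", {
  cfg <- mlp_config(hidden = 6, out = 4, act = "tanh")
  net <- build_network(cfg, seed = 16)
  X <- random_batch(c(1, 4, 4), 3, seed = 17)
  negatives <- list(2L, 3L, 1L)
  hcfg <- hinge_config(0.2, 2, 1, block_gradient = FALSE)
  B <- withr::with_seed(18, matrix(rnorm(4 * 3), 4, 3))
  lossf <- function(nn) {
    tr <- forward(nn, X)
    as.numeric(hinge_loss(tr$x[[3]], B, negatives, hcfg))
  }
  tr <- forward(net, X)
  err <- hinge_error_signals(tr$x[[3]], B, negatives, hcfg)
  err$blocked <- FALSE
  g <- branch_gradients(err)
  bw <- backward_errors(net, tr, g$grad_A, feedback_state("BP"))
  h <- 1e-6
  for (l in 2:3) {
    idx <- withr::with_seed(l, sample(length(bw$grads[[l]]), 10))
    for (i in idx) {
      np <- net; np$layers[[l]]$W[i] <- np$layers[[l]]$W[i] + h
      nm <- net; nm$layers[[l]]$W[i] <- nm$layers[[l]]$W[i] - h
      expect_equal(bw$grads[[l]][i], (lossf(np) - lossf(nm)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("RF training decreases the loss on a shallow network and alignment is reported", {
  ds <- small_synth(ipc = 20)
  cfg <- network_config(c(1, 28, 28), list(
    layer_spec("conv", channels = 8),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("flatten"),
    layer_spec("linear", channels = 16)), name = "shallow")
  net <- build_network(cfg, seed = 19)
  dc <- gray_deform()
  hc <- hinge_config_mnist(n_negatives = 3)
  l0 <- probe_hinge_loss(net, ds$train$images, dc, hc, probe_size = 24, seed = 77)
  fit <- train_e2e(net, ds$train$images, steps = 40, batch_size = 12,
                   deform_cfg = dc, loss_cfg = hc,
                   fb = feedback_state("RF", "adam", 1e-3), seed = 20)
  l1 <- probe_hinge_loss(fit$net, ds$train$images, dc, hc, probe_size = 24, seed = 77)
  expect_lt(l1, l0)

  tr <- forward(net, ds$train$images[, , , 1:6, drop = FALSE])
  td <- withr::with_seed(21, matrix(rnorm(16 * 6), 16, 6))
  al <- feedback_alignment(net, tr, td, feedback_state("RF"))
  expect_true(all(c("layer", "rule", "update_norm", "bp_alignment") %in% names(al)))
  expect_true(all(is.finite(al$bp_alignment)))
  expect_true(all(abs(al$bp_alignment) <= 1 + 1e-12))
})

test_that("missing feedback blocks are rejected under RF", {
  net <- build_network(mlp_config(), seed = 22)
  net$layers[[3]]$B <- NULL
  X <- random_batch(c(1, 4, 4), 2, seed = 23)
  tr <- forward(net, X)
  expect_error(backward_errors(net, tr, matrix(1, 6, 2), feedback_state("RF")),
               "feedback block")
})
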