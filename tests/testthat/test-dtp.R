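# Difference target propagation with pooling stages and learned inverses.

test_that("dtp forward equals the plain forward pass stage by stage", {
  dnet <- dtp_network(tiny_config(), seed = 1)
  X <- random_batch(c(1, 8, 8), 3, seed = 2)
  fwd <- dtp_forward(dnet, X)
  tr <- forward(dnet$net, X)
  ends <- vapply(dnet$stages, function(s) s[length(s)], integer(1))
  for (i in seq_along(ends))
    expect_identical(fwd$stage_x[[i + 1]], tr$x[[ends[i]]])
  # zero input, zero weights -> zero trace
  dz <- dnet
  for (l in seq_along(dz$net$layers))
    if (!is.null(dz$net$layers[[l]]$W)) dz$net$layers[[l]]$W[] <- 0
  fz <- dtp_forward(dz, X * 0)
  expect_true(all(vapply(fz$stage_x, function(x) all(x == 0), logical(1))))
})

test_that("a perfect inverse yields zero inverse loss and no update", {
  # two linear stages; g_2 initialized to the exact inverse of f_2
  cfg <- network_config(c(1, 2, 2), list(
    layer_spec("flatten"),
    layer_spec("linear", channels = 3, activation = "none"),
    layer_spec("linear", channels = 3)), name = "lin2")
  dnet <- dtp_network(cfg, seed = 3)
  W2 <- withr::with_seed(4, matrix(rnorm(9), 3, 3))
  dnet$net$layers[[3]]$W <- W2
  dnet$g[[2]]$V <- solve(W2)
  X <- random_batch(c(1, 2, 2), 4, seed = 5)
  fwd <- dtp_forward(dnet, X)
  ti <- train_inverses(dnet, fwd)
  expect_lt(ti$inverse_losses[2], 1e-20)
  expect_equal(ti$dnet$g[[2]]$V, solve(W2), tolerance = 1e-12)
})

test_that("inverse losses decrease over repeated steps on fixed data", {
  dnet <- dtp_network(tiny_config(), seed = 6, lr_inverse = 1e-2)
  X <- random_batch(c(1, 8, 8), 6, seed = 7)
  fwd <- dtp_forward(dnet, X)
  losses <- matrix(NA, 50, dnet$L)
  for (i in 1:50) {
    ti <- train_inverses(dnet, fwd)
    dnet <- ti$dnet
    losses[i, ] <- ti$inverse_losses
  }
  for (l in 2:dnet$L) {
    expect_lt(losses[50, l], losses[1, l])
    # convex least squares on a linear map: strictly decreasing trajectory
    expect_true(all(diff(losses[, l]) < 1e-12))
  }
})

test_that("inverse-loss gradients match central differences on a deconv stage", {
  dnet <- dtp_network(tiny_config(channels = c(2L, 3L), embedding = 4L), seed = 8)
  X <- random_batch(c(1, 8, 8), 2, seed = 9)
  fwd <- dtp_forward(dnet, X)
  l <- 2L
  x_prev <- fwd$stage_x[[l]]; x_l <- fwd$stage_x[[l + 1]]
  V <- dnet$g[[l]]$V
  lossV <- function(Vm) {
    gl <- dnet$g[[l]]; gl$V <- Vm
    sum((plausnet:::g_apply(gl, x_l) - x_prev)^2) / ncol(x_l)
  }
  # analytic gradient as used by train_inverses
  gl <- dnet$g[[l]]
  resid <- plausnet:::g_apply(gl, x_l) - x_prev
  r <- 2 * resid / ncol(x_l)
  Z2 <- matrix(x_l, nrow = nrow(V))
  dV <- plausnet:::conv_weight_grad(Z2, plausnet:::conv_patches(r, gl$geom))
  h <- 1e-6
  idx <- withr::with_seed(10, sample(length(V), 15))
  for (i in idx) {
    Vp <- V; Vm <- V; Vp[i] <- V[i] + h; Vm[i] <- V[i] - h
    expect_equal(dV[i], (lossV(Vp) - lossV(Vm)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("targets are a fixed point at zero top gradient and invert exactly with exact inverses", {
  dnet <- dtp_network(tiny_config(), seed = 11)
  X <- random_batch(c(1, 8, 8), 3, seed = 12)
  fwd <- dtp_forward(dnet, X)
  tg <- compute_targets(dnet, fwd, matrix(0, 10, 3))
  for (l in seq_len(dnet$L))
    expect_equal(tg[[l]], fwd$stage_x[[l + 1]], tolerance = 0)

  # exact linear inverses: xhat_{l-1} = g_l(xhat_l) (the correction cancels)
  cfg <- network_config(c(1, 2, 2), list(
    layer_spec("flatten"),
    layer_spec("linear", channels = 4, activation = "none"),
    layer_spec("linear", channels = 4)), name = "lin2b")
  dl <- dtp_network(cfg, seed = 13)
  W2 <- withr::with_seed(14, matrix(rnorm(16), 4, 4))
  dl$net$layers[[3]]$W <- W2
  dl$g[[2]]$V <- solve(W2)
  f2 <- dtp_forward(dl, random_batch(c(1, 2, 2), 3, seed = 15))
  grad <- withr::with_seed(16, matrix(rnorm(12), 4, 3))
  tg2 <- compute_targets(dl, f2, grad, eta = 0.05)
  expect_equal(tg2[[1]], plausnet:::g_apply(dl$g[[2]], tg2[[2]]), tolerance = 1e-12)
})

test_that("dtp_step matches a hand-unrolled transcription on a 2-stage linear toy", {
  cfg <- network_config(c(1, 2, 2), list(
    layer_spec("flatten"),
    layer_spec("linear", channels = 3, activation = "none"),
    layer_spec("linear", channels = 2)), name = "lin-toy")
  dnet <- dtp_network(cfg, seed = 17, lr_forward = 0.05, lr_inverse = 0.02,
                      optimizer = "sgd", eta_target = 0.1)
  W1 <- dnet$net$layers[[2]]$W     # 3 x 4
  W2 <- dnet$net$layers[[3]]$W     # 2 x 3
  V2 <- dnet$g[[2]]$V              # 3 x 2
  n <- 1L
  xA <- matrix(c(0.2, -0.4, 0.6, 0.1), 4, 1)
  xB <- matrix(c(0.5, 0.3, -0.2, 0.4), 4, 1)
  # 2-image batch where each anchor's negative is the other image
  vb <- structure(list(
    view_A = array(cbind(xA, xB), c(1, 2, 2, 2)),
    view_B = array(cbind(xB, xA), c(1, 2, 2, 2)),
    n = 2L, negatives = list(2L, 1L)), class = "view_batch")
  hcfg <- hinge_config(m1 = 0.1, m2 = 2, n_negatives = 1, block_gradient = TRUE)

  st <- dtp_step(dnet, vb, hcfg)

  ## straight-line transcription of the single-step algorithm (batch of the
  ## B branch drives learning under blocking; A enters only the loss signals)
  XA <- cbind(xA, xB); XB <- cbind(xB, xA)
  x1A <- W1 %*% XA; x2A <- W2 %*% x1A
  x1B <- W1 %*% XB; x2B <- W2 %*% x1B
  # hinge error signals (gradient w.r.t. each B embedding)
  gB <- matrix(0, 2, 2)
  for (s in 1:2) {
    dpos <- sum(abs(x2A[, s] - x2B[, s]))
    if (dpos > hcfg$m1) gB[, s] <- gB[, s] - sign(x2A[, s] - x2B[, s])
    t <- if (s == 1) 2 else 1
    dneg <- sum(abs(x2A[, t] - x2B[, s]))   # s is the negative of anchor t
    if (dneg < hcfg$m2) gB[, s] <- gB[, s] + sign(x2A[, t] - x2B[, s])
  }
  # inverse update on the B trace
  rec <- V2 %*% x2B
  V2n <- V2 - 0.02 * (2 * (rec - x1B) / 2) %*% t(x2B)
  # targets with the updated inverse
  gradB <- gB / 2
  xhat2 <- x2B - 0.1 * gradB
  xhat1 <- x1B - V2n %*% x2B + V2n %*% xhat2
  # forward updates: stage 1 on the local loss, stage 2 on the global loss
  d1 <- 2 * (x1B - xhat1) / 2
  W1n <- W1 - 0.05 * d1 %*% t(XB)
  W2n <- W2 - 0.05 * gradB %*% t(x1B)

  expect_equal(st$dnet$g[[2]]$V, V2n, tolerance = 1e-9)
  expect_equal(st$dnet$net$layers[[2]]$W, W1n, tolerance = 1e-9)
  expect_equal(st$dnet$net$layers[[3]]$W, W2n, tolerance = 1e-9)
})

test_that("zero top gradient leaves lower stages untouched in a dtp step", {
  dnet <- dtp_network(tiny_config(), seed = 18, optimizer = "sgd")
  X <- random_batch(c(1, 8, 8), 4, seed = 19)
  # identical branches at margin settings where nothing is active
  vb <- structure(list(view_A = X, view_B = X, n = 4L,
                       negatives = lapply(1:4, function(s) select_negatives(4, 1, s))),
                  class = "view_batch")
  # distances: positives 0 (inactive for m1 > 0); force negatives inactive
  hcfg <- hinge_config(m1 = 0.5, m2 = 1e-9, n_negatives = 1)
  before <- lapply(dnet$net$layers, `[[`, "W")
  st <- dtp_step(dnet, vb, hcfg)
  expect_equal(st$loss, 0)
  expect_true(all(st$local_losses[seq_len(dnet$L - 1)] < 1e-20))
  after <- lapply(st$dnet$net$layers, `[[`, "W")
  for (l in seq_along(before))
    if (!is.null(before[[l]])) expect_equal(after[[l]], before[[l]], tolerance = 0)
})

test_that("stage-l updates never read the forward weights above (asymmetry contract)", {
  dnet <- dtp_network(tiny_config(), seed = 20, optimizer = "sgd")
  X <- random_batch(c(1, 8, 8), 4, seed = 21)
  dc <- deformation_config(crop_scale_range = c(0.8, 1), aspect_range = c(1, 1),
                           flip_prob = 0, jitter_strengths = c(0, 0, 0, 0),
                           jitter_prob = 0, grayscale_prob = 0, seed = 22)
  vb <- make_views(X, dc, n_negatives = 2)
  hcfg <- hinge_config(1, 3, 2)

  fwdB <- dtp_forward(dnet, vb$view_B)
  # compute stage-1 local gradient from targets, then corrupt W of all upper
  # stages and recompute: the stage-1 update must be identical because credit
  # reaches it only through the (fixed) targets
  emb_A <- dtp_forward(dnet, vb$view_A)$stage_x[[dnet$L + 1]]
  err <- hinge_error_signals(emb_A, fwdB$stage_x[[dnet$L + 1]], vb$negatives, hcfg)
  g <- branch_gradients(err)
  tg <- compute_targets(dnet, fwdB, g$grad_B / 4)
  w1 <- plausnet:::stage_local_grad(dnet, fwdB, 1, tg[[1]])

  dnet2 <- dnet
  for (l in seq_along(dnet2$net$layers))
    if (!is.null(dnet2$net$layers[[l]]$W) && l > max(dnet2$stages[[1]]))
      dnet2$net$layers[[l]]$W <- dnet2$net$layers[[l]]$W * 3 + 1
  w1b <- plausnet:::stage_local_grad(dnet2, fwdB, 1, tg[[1]])
  expect_identical(w1$grad, w1b$grad)
})

test_that("dtp training reduces the contrastive hinge loss on synthetic data", {
  ds <- small_synth(ipc = 25)
  dnet <- dtp_network(config_mnist_encoder(channels = c(8L, 12L, 16L)), seed = 23,
                      lr_forward = 1e-3, optimizer = "adam")
  dc <- gray_deform()
  hc <- hinge_config_mnist(n_negatives = 3)
  l0 <- probe_hinge_loss(dnet$net, ds$train$images, dc, hc, probe_size = 24, seed = 88)
  fit <- dtp_train(dnet, ds$train$images, steps = 60, batch_size = 12,
                   deform_cfg = dc, loss_cfg = hc, seed = 24)
  l1 <- probe_hinge_loss(fit$dnet$net, ds$train$images, dc, hc, probe_size = 24, seed = 88)
  expect_lt(l1, l0)
})
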