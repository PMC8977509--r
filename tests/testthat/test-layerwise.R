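# Greedy and randomized layer-wise training.

lw_fixture <- function(ipc = 20, seed = 7) {
  list(ds = small_synth(ipc = ipc, seed = seed),
       cfg = config_mnist_encoder(channels = c(6L, 8L, 10L)),
       dc = gray_deform(),
       hc = hinge_config_mnist(n_negatives = 3))
}

test_that("GLL reduces each stage's training loss from its start to its end", {
  fx <- lw_fixture()
  net0 <- build_network(fx$cfg, seed = 1)
  fit <- gll_train(net0, images = fx$ds$train$images, steps_per_stage = 40,
                   batch_size = 10, deform_cfg = fx$dc, loss_cfg = fx$hc,
                   rule = "BP", seed = 3)
  expect_equal(sort(unique(fit$history$stage)), 1:3)
  for (k in unique(fit$history$stage)) {
    hs <- fit$history[fit$history$stage == k, ]
    expect_lt(mean(tail(hs$loss, 8)), mean(head(hs$loss, 8)))
  }
})

test_that("a GLL stage update touches exactly the stage conv and its head", {
  fx <- lw_fixture(ipc = 10)
  net <- build_network(fx$cfg, seed = 4)
  lay <- plausnet:::stage_layout(net)
  heads <- build_aux_heads(net, seed = 5)
  vb <- make_views(fx$ds$train$images[, , , 1:8, drop = FALSE],
                   fx$dc, n_negatives = 3)
  k <- 2L
  st <- plausnet:::layerwise_step(net, heads, k, lay, vb, fx$hc,
                                  feedback_state("BP", "adam", 1e-3),
                                  feedback_state("BP", "adam", 1e-3))
  trained_layer <- lay$trainables[k]
  for (l in seq_along(net$layers)) {
    if (is.null(net$layers[[l]]$W)) next
    if (l == trained_layer) {
      expect_false(identical(st$net$layers[[l]]$W, net$layers[[l]]$W))
    } else {
      expect_identical(st$net$layers[[l]]$W, net$layers[[l]]$W)
    }
  }
  expect_false(identical(st$heads[[k]]$W, heads[[k]]$W))
  for (j in seq_along(heads)) if (j != k)
    expect_identical(st$heads[[j]]$W, heads[[j]]$W)
})

test_that("updating stage k never reads weights above it except its own head", {
  # corrupt all layers above stage k: the stage-k update must be unchanged
  fx <- lw_fixture(ipc = 10)
  net <- build_network(fx$cfg, seed = 6)
  lay <- plausnet:::stage_layout(net)
  heads <- build_aux_heads(net, seed = 7)
  vb <- make_views(fx$ds$train$images[, , , 1:8, drop = FALSE],
                   fx$dc, n_negatives = 3)
  k <- 1L
  st1 <- plausnet:::layerwise_step(net, heads, k, lay, vb, fx$hc,
                                   feedback_state("BP", "sgd", 1e-2),
                                   feedback_state("BP", "sgd", 1e-2))
  net2 <- net
  above <- setdiff(seq_along(net$layers), lay$encoder_stages[[k]])
  for (l in above) if (!is.null(net2$layers[[l]]$W))
    net2$layers[[l]]$W <- net2$layers[[l]]$W * 5 + 2
  st2 <- plausnet:::layerwise_step(net2, heads, k, lay, vb, fx$hc,
                                   feedback_state("BP", "sgd", 1e-2),
                                   feedback_state("BP", "sgd", 1e-2))
  tl <- lay$trainables[k]
  expect_identical(st1$net$layers[[tl]]$W, st2$net$layers[[tl]]$W)
  expect_identical(st1$heads[[k]]$W, st2$heads[[k]]$W)
})

test_that("RLL draws layers uniformly and updates only the drawn pair", {
  fx <- lw_fixture(ipc = 10)
  net <- build_network(fx$cfg, seed = 8)
  fit <- rll_train(net, images = fx$ds$train$images, steps = 60, batch_size = 8,
                   deform_cfg = fx$dc, loss_cfg = fx$hc, rule = "BP", seed = 9)
  expect_length(fit$draws, 60)
  expect_setequal(sort(unique(fit$draws)), 1:3)

  # frequency uniformity over many cheap draws (the sampling path itself)
  draws <- vapply(1:3000, function(i) withr::with_seed(i, sample.int(3L, 1L)), integer(1))
  tab <- table(draws)
  chi <- sum((tab - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("every rule reduces the loss under both layer-wise modes", {
  fx <- lw_fixture(ipc = 15)
  imgs <- fx$ds$train$images
  l0 <- probe_hinge_loss(build_network(fx$cfg, seed = 11), imgs, fx$dc, fx$hc,
                         probe_size = 20, seed = 55)
  for (rule in c("BP", "RF", "URF")) {
    g <- gll_train(build_network(fx$cfg, seed = 11), images = imgs,
                   steps_per_stage = 20, batch_size = 10, deform_cfg = fx$dc,
                   loss_cfg = fx$hc, rule = rule, seed = 12)
    expect_lt(probe_hinge_loss(g$net, imgs, fx$dc, fx$hc, probe_size = 20, seed = 55),
              l0)
    r <- rll_train(build_network(fx$cfg, seed = 11), images = imgs,
                   steps = 60, batch_size = 10, deform_cfg = fx$dc,
                   loss_cfg = fx$hc, rule = rule, seed = 13)
    expect_lt(probe_hinge_loss(r$net, imgs, fx$dc, fx$hc, probe_size = 20, seed = 55),
              l0)
  }
})

test_that("a one-stage network trained with GLL+BP matches end-to-end BP step for step", {
  cfg <- network_config(c(1, 8, 8), list(
    layer_spec("conv", channels = 4),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("flatten"),
    layer_spec("linear", channels = 8)), name = "one-stage")
  X <- random_batch(c(1, 8, 8), 12, seed = 14)
  dc <- deformation_config(crop_scale_range = c(0.7, 1), aspect_range = c(1, 1),
                           flip_prob = 0.5, jitter_strengths = c(0, 0, 0, 0),
                           jitter_prob = 0, grayscale_prob = 0)
  hc <- hinge_config(0.5, 2, 2)
  # E2E on this net updates conv + head; GLL's single stage is the conv with
  # its aux head. With the aux head initialized to the network's own head
  # weights, the two runs see identical gradients.
  net_e <- build_network(cfg, seed = 15)
  fit_e <- train_e2e(net_e, X, steps = 8, batch_size = 8, deform_cfg = dc,
                     loss_cfg = hc, fb = feedback_state("BP", "sgd", 1e-2),
                     seed = 16)
  net_g <- build_network(cfg, seed = 15)
  heads <- build_aux_heads(net_g, embedding_dim = 8, seed = 17)
  heads[[1]]$W <- net_g$layers[[4]]$W
  heads[[1]]$B <- net_g$layers[[4]]$B
  fit_g <- gll_train(net_g, heads, X, steps_per_stage = 8, batch_size = 8,
                     deform_cfg = dc, loss_cfg = hc, rule = "BP",
                     optimizer = "sgd", lr = 1e-2, seed = 16)
  expect_equal(fit_g$net$layers[[1]]$W, fit_e$net$layers[[1]]$W, tolerance = 1e-12)
  expect_equal(fit_g$heads[[1]]$W, fit_e$net$layers[[4]]$W, tolerance = 1e-12)
  expect_equal(fit_g$history$loss, fit_e$history$loss, tolerance = 1e-10)
})
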