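# Desk-scale studies: mechanism-by-mechanism loss-reduction comparison and
# the representation/robustness ordering study. These drive the package's
# trainers under one shared fixture and report tidy summaries.

# chunked feature extraction so large sets do not materialize huge im2col
# buffers at once
embed_chunks <- function(net, images, strip_head = TRUE, chunk = 128L) {
  n <- dim(images)[4]
  parts <- lapply(seq(1L, n, by = chunk), function(s) {
    idx <- s:min(s + chunk - 1L, n)
    embed(net, images[, , , idx, drop = FALSE], strip_head = strip_head)
  })
  do.call(cbind, parts)
}

#' Compare training mechanisms on one synthetic fixture
#'
#' Trains every requested trainer/rule combination from the same
#' initialization on the same image set and reports the contrastive hinge
#' loss on a fixed probe batch before and after training — the desk-scale
#' analogue of comparing loss trajectories across credit-assignment
#' mechanisms.
#'
#' @param images Training images `(C, H, W, N)`.
#' @param config Encoder [network_config()].
#' @param combos Data frame with columns `trainer`, `rule`; defaults to all
#'   E2E/GLL/RLL x BP/RF/URF plus DTP.
#' @param steps Update steps per combination.
#' @param batch_size,deform_cfg,loss_cfg,lr As in the trainers.
#' @param seed Integer master seed.
#' @return Tibble: `trainer`, `rule`, `loss_before`, `loss_after`,
#'   `reduction` (fraction of the initial loss removed).
#' @export
run_mechanism_comparison <- function(images, config = config_mnist_encoder(),
                                     combos = NULL, steps = 200L,
                                     batch_size = 16L,
                                     deform_cfg = deformation_config(),
                                     loss_cfg = hinge_config_mnist(),
                                     lr = 1e-4, seed = 1L) {
  if (is.null(combos))
    combos <- rbind(expand.grid(trainer = c("E2E", "GLL", "RLL"),
                                rule = c("BP", "RF", "URF"),
                                stringsAsFactors = FALSE),
                    data.frame(trainer = "DTP", rule = "BP"))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    trainer <- combos$trainer[i]; rule <- combos$rule[i]
    net0 <- build_network(config, seed)
    # layer-wise trainers optimize their top auxiliary head, not the
    # network's projection head; measure each trainer's own objective
    head0 <- head1 <- NULL
    if (trainer %in% c("GLL", "RLL")) {
      K <- length(stage_layout(net0)$encoder_stages)
      heads <- build_aux_heads(net0, seed = seed)
      head0 <- heads[[K]]
    }
    l0 <- probe_hinge_loss(net0, images, deform_cfg, loss_cfg,
                           seed = seed + 17L, head = head0)
    net1 <- switch(trainer,
      E2E = train_e2e(net0, images, steps = steps, batch_size = batch_size,
                      deform_cfg = deform_cfg, loss_cfg = loss_cfg,
                      fb = feedback_state(rule, "adam", lr),
                      seed = seed + i)$net,
      GLL = {
        K <- length(stage_layout(net0)$encoder_stages)
        fit <- gll_train(net0, heads, images = images,
                         steps_per_stage = max(1L, steps %/% K),
                         batch_size = batch_size, deform_cfg = deform_cfg,
                         loss_cfg = loss_cfg, rule = rule, lr = lr,
                         seed = seed + i)
        head1 <- fit$heads[[K]]
        fit$net
      },
      RLL = {
        K <- length(stage_layout(net0)$encoder_stages)
        fit <- rll_train(net0, heads, images = images, steps = steps,
                         batch_size = batch_size, deform_cfg = deform_cfg,
                         loss_cfg = loss_cfg, rule = rule, lr = lr,
                         seed = seed + i)
        head1 <- fit$heads[[K]]
        fit$net
      },
      DTP = {
        dnet <- dtp_network(config, seed = seed, lr_forward = lr,
                            optimizer = "adam")
        dtp_train(dnet, images, steps = steps, batch_size = batch_size,
                  deform_cfg = deform_cfg, loss_cfg = loss_cfg,
                  seed = seed + i)$dnet$net
      })
    l1 <- probe_hinge_loss(net1, images, deform_cfg, loss_cfg,
                           seed = seed + 17L, head = head1)
    rows[[i]] <- tibble::tibble(trainer = trainer, rule = rule,
                                loss_before = l0, loss_after = l1,
                                reduction = 1 - l1 / l0)
  }
  do.call(rbind, rows)
}

#' Representation and robustness ordering study
#'
#' For each seed: pretrains an encoder with the contrastive hinge loss,
#' probes it and a random (untrained) encoder with identical linear
#' classifiers, and compares the SSL probe against a supervised end-to-end
#' baseline on an affine-deformed copy of the test set (deformations unseen
#' by either classifier's training data).
#'
#' @param dataset A `synthetic_dataset` (defaults to the standard fixture).
#' @param config Encoder [network_config()].
#' @param seeds Integer vector of study seeds.
#' @param pretrain_steps,supervised_steps Encoder training lengths.
#' @param probe_epochs Linear classifier epochs.
#' @param batch_size,deform_cfg,loss_cfg As in the trainers.
#' @return Tibble, one row per seed: `trained_probe`, `random_probe`,
#'   `ssl_robustness`, `supervised_robustness`.
#' @export
run_representation_study <- function(dataset = NULL,
                                     config = config_mnist_encoder(),
                                     seeds = 1:5,
                                     pretrain_steps = 150L,
                                     supervised_steps = 150L,
                                     probe_epochs = 30L,
                                     batch_size = 16L,
                                     deform_cfg = NULL,
                                     loss_cfg = hinge_config_mnist()) {
  if (is.null(dataset)) dataset <- generate_synthetic(synthetic_spec())
  if (is.null(deform_cfg))
    deform_cfg <- deformation_config(
      crop_scale_range = c(0.5, 1), flip_prob = 0.5,
      jitter_strengths = c(0.4, 0.4, 0, 0), grayscale_prob = 0)
  train <- dataset$train; test <- dataset$test
  K <- max(train$labels)
  sup_cfg <- config
  sup_cfg$layers[[length(sup_cfg$layers)]]$channels <- as.integer(K)
  sup_cfg <- network_config(sup_cfg$input_shape, sup_cfg$layers, name = "supervised")
  rows <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    sd <- seeds[i]
    net_r <- build_network(config, sd)
    fit <- train_e2e(build_network(config, sd), train$images,
                     steps = pretrain_steps, batch_size = batch_size,
                     deform_cfg = deform_cfg, loss_cfg = loss_cfg,
                     fb = feedback_state("BP", "adam", 1e-3), seed = sd)
    deformed <- deform_test_set(test$images, affine_config(seed = sd + 100L))
    probe <- function(nn) {
      ftr <- embed_chunks(nn, train$images)
      fte <- embed_chunks(nn, test$images)
      fde <- embed_chunks(nn, deformed)
      clf <- train_linear_classifier(ftr, train$labels, epochs = probe_epochs,
                                     seed = sd)
      c(plain = classifier_accuracy(clf, fte, test$labels),
        deformed = classifier_accuracy(clf, fde, test$labels))
    }
    acc_t <- probe(fit$net)
    acc_r <- probe(net_r)
    sup <- train_supervised(build_network(sup_cfg, sd), train$images,
                            train$labels, steps = supervised_steps,
                            batch_size = batch_size,
                            fb = feedback_state("BP", "adam", 1e-3), seed = sd)
    Zs <- embed_chunks(sup$net, deformed, strip_head = FALSE)
    sup_rob <- mean(max.col(t(Zs)) == test$labels)
    rows[[i]] <- tibble::tibble(seed = sd,
                                trained_probe = unname(acc_t["plain"]),
                                random_probe = unname(acc_r["plain"]),
                                ssl_robustness = unname(acc_t["deformed"]),
                                supervised_robustness = sup_rob)
  }
  do.call(rbind, rows)
}
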