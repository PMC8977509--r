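# End-to-end trainers: self-supervised (contrastive hinge or SimCLR-style
# evaluation is external) and a supervised baseline used by the robustness
# protocol.

# per-step derived seeds, kept within 32-bit integer range
derive_seeds <- function(seed, k) with_seed(seed, sample.int(2147483646L, k))

sample_batch_idx <- function(N, batch_size) {
  if (batch_size >= N) seq_len(N) else sample.int(N, batch_size)
}

#' One end-to-end SSL update on a view batch
#'
#' Forwards both branches, computes the contrastive hinge loss and its error
#' signals, propagates them with the configured rule and applies one
#' optimizer step (gradients accumulated over the branches; the anchor branch
#' contributes nothing under gradient blocking).
#'
#' @param net A `plausnet_network`.
#' @param vb A `view_batch` with negative sets.
#' @param loss_cfg A [hinge_config()].
#' @param fb A [feedback_state()].
#' @return List: `net`, `fb`, `loss`, `pos_sum`, `neg_sum`, `active_pos`,
#'   `active_neg`.
#' @export
ssl_step <- function(net, vb, loss_cfg, fb) {
  if (is.null(vb$negatives)) contract_error("view batch has no negative sets")
  tr_A <- forward(net, vb$view_A)
  tr_B <- forward(net, vb$view_B)
  emb_A <- tr_A$x[[net$L]]
  emb_B <- tr_B$x[[net$L]]
  loss <- hinge_loss(emb_A, emb_B, vb$negatives, loss_cfg)
  bk <- attr(loss, "breakdown")
  err <- hinge_error_signals(emb_A, emb_B, vb$negatives, loss_cfg)
  err$blocked <- loss_cfg$block_gradient
  g <- branch_gradients(err)
  bw_B <- backward_errors(net, tr_B, g$grad_B, fb)
  grads <- bw_B$grads
  if (!loss_cfg$block_gradient && any(g$grad_A != 0)) {
    bw_A <- backward_errors(net, tr_A, g$grad_A, fb)
    for (l in seq_along(grads))
      if (!is.null(grads[[l]])) grads[[l]] <- grads[[l]] + bw_A$grads[[l]]
  }
  st <- optimizer_step(net, grads, fb)
  pos <- bk[is.na(bk$negative), ]; neg <- bk[!is.na(bk$negative), ]
  list(net = st$net, fb = st$fb, loss = as.numeric(loss),
       pos_sum = sum(pos$term), neg_sum = sum(neg$term),
       active_pos = sum(pos$term > 0), active_neg = sum(neg$term > 0))
}

#' Train an encoder end-to-end with the contrastive hinge loss
#'
#' @param net A `plausnet_network` (built fresh or resumed).
#' @param images Array `(C, H, W, N)` of unlabeled training images in \[0,1\].
#' @param steps Number of update steps (one random batch each).
#' @param batch_size Images per batch.
#' @param deform_cfg A [deformation_config()]; its seed is re-derived per
#'   step from `seed` so every step sees fresh deformations.
#' @param loss_cfg A [hinge_config()].
#' @param fb A [feedback_state()].
#' @param seed Master seed for batch sampling and deformation streams.
#' @param log_csv Optional path; per-step diagnostics appended as CSV.
#' @return List: `net`, `fb`, `history` (tibble: step, loss, pos_sum,
#'   neg_sum, active_pos, active_neg).
#' @export
train_e2e <- function(net, images, steps = 200L, batch_size = 16L,
                      deform_cfg = deformation_config(),
                      loss_cfg = hinge_config(),
                      fb = feedback_state("BP"),
                      seed = 1L, log_csv = NULL) {
  N <- dim(images)[4]
  seeds <- derive_seeds(seed, 2L * steps)
  hist <- vector("list", steps)
  for (step in seq_len(steps)) {
    idx <- with_seed(seeds[2L * step - 1L], sample_batch_idx(N, batch_size))
    dc <- deform_cfg; dc$seed <- seeds[2L * step]
    vb <- make_views(images[, , , idx, drop = FALSE], dc,
                     n_negatives = loss_cfg$n_negatives)
    st <- ssl_step(net, vb, loss_cfg, fb)
    net <- st$net; fb <- st$fb
    hist[[step]] <- tibble::tibble(step = step, loss = st$loss,
                                   pos_sum = st$pos_sum, neg_sum = st$neg_sum,
                                   active_pos = st$active_pos,
                                   active_neg = st$active_neg)
  }
  history <- do.call(rbind, hist)
  if (!is.null(log_csv))
    utils::write.table(history, log_csv, sep = ",", row.names = FALSE,
                       col.names = !file.exists(log_csv), append = file.exists(log_csv))
  list(net = net, fb = fb, history = history)
}

#' Evaluate the contrastive hinge loss on a fixed probe batch
#'
#' Deterministic measurement used to compare loss before and after training:
#' a fixed view batch is built from `seed` and the summed hinge loss of the
#' current encoder on it is returned.
#'
#' @inheritParams train_e2e
#' @param probe_size Number of images in the probe batch.
#' @param head Optional auxiliary head (list with `W`): embeddings are then
#'   computed as `head$W` applied to the flattened last-conv-block features,
#'   the objective a layer-wise trainer actually optimizes at its top stage.
#' @return Loss scalar.
#' @export
probe_hinge_loss <- function(net, images, deform_cfg = deformation_config(),
                             loss_cfg = hinge_config(), probe_size = 32L,
                             seed = 999L, head = NULL) {
  N <- dim(images)[4]
  idx <- with_seed(seed, sample_batch_idx(N, probe_size))
  dc <- deform_cfg; dc$seed <- seed
  vb <- make_views(images[, , , idx, drop = FALSE], dc,
                   n_negatives = loss_cfg$n_negatives)
  emb <- function(batch) {
    if (is.null(head)) embed(net, batch)
    else head$W %*% embed(net, batch, strip_head = TRUE)
  }
  as.numeric(hinge_loss(emb(vb$view_A), emb(vb$view_B), vb$negatives, loss_cfg))
}

# softmax over columns
softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max), `-`)
  E <- exp(Z)
  sweep(E, 2, colSums(E), `/`)
}

#' Train a supervised network end-to-end (baseline)
#'
#' Same layer machinery, BP with softmax cross-entropy on the labeled set;
#' serves as the comparison arm of the robustness protocol. The network's
#' top linear layer width must equal the number of classes.
#'
#' @param net A `plausnet_network` whose head width equals `max(labels)`.
#' @param images Array `(C, H, W, N)`.
#' @param labels Integer labels `1..K`.
#' @param steps,batch_size,seed As in [train_e2e()].
#' @param fb A [feedback_state()] (rule BP for the standard baseline).
#' @return List: `net`, `fb`, `history` (tibble: step, loss, accuracy).
#' @export
train_supervised <- function(net, images, labels, steps = 200L, batch_size = 32L,
                             fb = feedback_state("BP"), seed = 1L) {
  N <- dim(images)[4]
  K <- net$layers[[net$L]]$spec$channels
  if (max(labels) > K) contract_error("head width ", K, " < number of classes")
  seeds <- derive_seeds(seed, steps)
  hist <- vector("list", steps)
  for (step in seq_len(steps)) {
    idx <- with_seed(seeds[step], sample_batch_idx(N, batch_size))
    tr <- forward(net, images[, , , idx, drop = FALSE])
    n <- tr$n
    P <- softmax_cols(tr$x[[net$L]])
    Y <- matrix(0, K, n); Y[cbind(labels[idx], seq_len(n))] <- 1
    loss <- -sum(log(pmax(P[Y == 1], 1e-12))) / n
    d_top <- (P - Y) / n
    bw <- backward_errors(net, tr, d_top, fb)
    st <- optimizer_step(net, bw$grads, fb)
    net <- st$net; fb <- st$fb
    hist[[step]] <- tibble::tibble(step = step, loss = loss,
                                   accuracy = mean(max.col(t(P)) == labels[idx]))
  }
  list(net = net, fb = fb, history = do.call(rbind, hist))
}

#' Plot a training-loss history
#'
#' @param history Tibble with columns `step` and `loss` (as returned by the
#'   trainers), optionally `stage`.
#' @return A ggplot object.
#' @export
plot_loss_history <- function(history) {
  p <- ggplot2::ggplot(history, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "training step", y = "contrastive hinge loss") +
    ggplot2::theme_minimal()
  if ("stage" %in% names(history))
    p <- p + ggplot2::aes(color = factor(.data$stage)) +
      ggplot2::labs(color = "stage")
  p
}
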