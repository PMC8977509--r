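# Greedy (GLL) and randomized (RLL) layer-wise training. Each trainable
# encoder stage (a convolution plus its following pooling/activation layers)
# gets an auxiliary head (flatten + linear to the embedding space); at any
# step exactly one stage and its head are updated, via a one-hidden-layer
# error propagation with BP, RF or URF feedback from head to stage.

# Stage decomposition: each stage starts at a trainable layer and absorbs the
# following non-trainable layers; leading non-trainables attach to the next
# stage. The final stage (flatten + linear projection head) is the encoder's
# own head and is excluded from `encoder_stages`.
stage_layout <- function(net) {
  kinds <- vapply(net$layers, function(l) l$spec$kind, character(1))
  trainable <- which(kinds %in% c("conv", "linear"))
  stages <- vector("list", length(trainable))
  start <- 1L
  for (j in seq_along(trainable)) {
    t <- trainable[j]
    nxt <- if (j < length(trainable)) trainable[j + 1L] else net$L + 1L
    span_end <- nxt - 1L
    between <- seq_len(net$L)[seq_len(net$L) > t & seq_len(net$L) < nxt]
    fl <- between[kinds[between] == "flatten"]
    if (length(fl)) span_end <- fl[1] - 1L   # flatten opens the next stage
    stages[[j]] <- seq(start, span_end)
    start <- span_end + 1L
  }
  # index of the trainable layer within each stage span
  list(stages = stages,
       trainables = trainable,
       encoder_stages = stages[-length(stages)],
       head_stage = stages[[length(stages)]])
}

# forward through a span of layers; returns local h/x/cache lists + output
forward_span <- function(net, X, span) {
  n <- ncol(X)
  h <- list(); x <- list(); cache <- list()
  cur <- X
  for (i in seq_along(span)) {
    l <- span[i]
    ly <- net$layers[[l]]
    hl <- switch(ly$spec$kind,
      conv = {
        p <- conv_patches(cur, ly$geom)
        cache[[i]] <- list(patches = p)
        conv_forward(ly$W, p, ly$geom, n)
      },
      linear = ly$W %*% cur,
      maxpool = {
        mp <- maxpool_forward(cur, ly$geom)
        cache[[i]] <- list(win = mp$win)
        mp$Y
      },
      avgpool = avgpool_forward(cur, ly$geom),
      flatten = cur)
    xl <- act_fun(hl, ly$spec$activation)
    h[[i]] <- hl; x[[i]] <- xl
    cur <- xl
  }
  list(h = h, x = x, cache = cache, out = cur, span = span, n = n)
}

# gradient of the span's trainable layer weights given the gradient w.r.t.
# the span output (post-activation); propagates only within the span.
span_weight_grad <- function(net, sp, g_out) {
  n <- sp$n
  d <- g_out
  for (i in rev(seq_along(sp$span))) {
    l <- sp$span[i]
    ly <- net$layers[[l]]
    d <- d * act_deriv(sp$h[[i]], ly$spec$activation)
    if (ly$spec$kind == "conv") {
      D2 <- matrix(d, nrow = ly$spec$channels)
      return(list(layer = l, grad = conv_weight_grad(D2, sp$cache[[i]]$patches)))
    }
    if (ly$spec$kind == "linear") {
      x_prev <- if (i > 1L) sp$x[[i - 1L]] else sp$input
      return(list(layer = l, grad = tcrossprod(d, x_prev)))
    }
    d <- switch(ly$spec$kind,
      maxpool = maxpool_backward(d, sp$cache[[i]]$win, ly$geom, n),
      avgpool = avgpool_backward(d, ly$geom, n),
      flatten = d)
  }
  contract_error("span has no trainable layer")
}

# auxiliary head: flatten + linear to the embedding space, with independent
# feedback block (transposed orientation)
build_head <- function(d_in, embedding_dim, seed) {
  bnd <- 1 / sqrt(d_in)
  with_seed(seed, list(
    W = matrix(runif(embedding_dim * d_in, -bnd, bnd), embedding_dim, d_in),
    B = matrix(runif(d_in * embedding_dim, -bnd, bnd), d_in, embedding_dim)))
}

#' Build auxiliary heads for every encoder stage
#'
#' @param net A `plausnet_network`.
#' @param embedding_dim Embedding width of each head.
#' @param seed Integer seed.
#' @return List of heads (`W`, `B`), one per encoder stage.
#' @export
build_aux_heads <- function(net, embedding_dim = 64L, seed = 1L) {
  lay <- stage_layout(net)
  seeds <- derive_seeds(seed, length(lay$encoder_stages))
  lapply(seq_along(lay$encoder_stages), function(k) {
    span <- lay$encoder_stages[[k]]
    d_in <- prod(net$layers[[span[length(span)]]]$shape_out)
    build_head(d_in, embedding_dim, seeds[k])
  })
}

# one layer-wise update of stage k (and its head) on a view batch;
# fb_stage / fb_head carry optimizer state per parameter block
layerwise_step <- function(net, heads, k, lay, vb, loss_cfg, fb_stage, fb_head) {
  span <- lay$encoder_stages[[k]]
  pre <- if (span[1] > 1L) seq_len(span[1] - 1L) else integer(0)
  run_branch <- function(batch) {
    X <- as_flat_batch(batch, net$config$input_shape)
    if (length(pre)) X <- forward_span(net, X, pre)$out
    sp <- forward_span(net, X, span)
    sp$input <- X
    emb <- heads[[k]]$W %*% sp$out
    list(sp = sp, emb = emb)
  }
  brA <- run_branch(vb$view_A)
  brB <- run_branch(vb$view_B)
  loss <- hinge_loss(brA$emb, brB$emb, vb$negatives, loss_cfg)
  err <- hinge_error_signals(brA$emb, brB$emb, vb$negatives, loss_cfg)
  err$blocked <- loss_cfg$block_gradient
  g <- branch_gradients(err)
  head <- heads[[k]]
  gW_head <- matrix(0, nrow(head$W), ncol(head$W))
  g_stage <- NULL
  acc <- function(br, gr) {
    gW_head <<- gW_head + tcrossprod(gr, br$sp$out)
    g_out <- if (fb_stage$rule == "BP") crossprod(head$W, gr) else head$B %*% gr
    wg <- span_weight_grad(net, br$sp, g_out)
    g_stage <<- if (is.null(g_stage)) wg else list(layer = wg$layer, grad = g_stage$grad + wg$grad)
  }
  acc(brB, g$grad_B)
  if (!loss_cfg$block_gradient && any(g$grad_A != 0)) acc(brA, g$grad_A)
  # stage update
  grads <- vector("list", net$L)
  grads[[g_stage$layer]] <- g_stage$grad
  st <- optimizer_step(net, grads, fb_stage)
  net <- st$net; fb_stage <- st$fb
  # head update (its own tiny "network": apply the same optimizer inline)
  hstep <- optimizer_step(structure(list(layers = list(list(W = head$W, B = head$B)), L = 1L,
                                         config = net$config),
                                    class = "plausnet_network"),
                          list(gW_head), fb_head)
  heads[[k]]$W <- hstep$net$layers[[1]]$W
  heads[[k]]$B <- hstep$net$layers[[1]]$B
  fb_head <- hstep$fb
  list(net = net, heads = heads, fb_stage = fb_stage, fb_head = fb_head,
       loss = as.numeric(loss))
}

make_layerwise_states <- function(n_stages, rule, optimizer, lr) {
  list(stage = lapply(seq_len(n_stages), function(i) feedback_state(rule, optimizer, lr)),
       head = lapply(seq_len(n_stages), function(i) feedback_state(rule, optimizer, lr)))
}

#' Greedy layer-wise SSL training
#'
#' Trains encoder stages strictly bottom-to-top: for stage l, layers below
#' are frozen, and only stage l plus its auxiliary head are updated, with a
#' one-hidden-layer error propagation under the chosen rule.
#'
#' @param net A `plausnet_network`.
#' @param heads Auxiliary heads from [build_aux_heads()] (`NULL` builds them).
#' @param images Unlabeled training images `(C, H, W, N)`.
#' @param steps_per_stage Update steps per stage.
#' @param batch_size Images per batch.
#' @param deform_cfg,loss_cfg,seed As in [train_e2e()].
#' @param rule Feedback rule for the one-layer propagation.
#' @param optimizer,lr Optimizer preset for stages and heads.
#' @return List: `net`, `heads`, `history` (tibble with `stage`, `step`,
#'   `loss`).
#' @export
gll_train <- function(net, heads = NULL, images, steps_per_stage = 50L,
                      batch_size = 16L, deform_cfg = deformation_config(),
                      loss_cfg = hinge_config(), rule = "BP",
                      optimizer = "adam", lr = 1e-3, seed = 1L) {
  lay <- stage_layout(net)
  if (is.null(heads)) heads <- build_aux_heads(net, seed = seed)
  K <- length(lay$encoder_stages)
  states <- make_layerwise_states(K, rule, optimizer, lr)
  N <- dim(images)[4]
  seeds <- derive_seeds(seed, 2L * K * steps_per_stage)
  hist <- list()
  i <- 0L
  for (k in seq_len(K)) {
    for (step in seq_len(steps_per_stage)) {
      i <- i + 1L
      idx <- with_seed(seeds[2L * i - 1L], sample_batch_idx(N, batch_size))
      dc <- deform_cfg; dc$seed <- seeds[2L * i]
      vb <- make_views(images[, , , idx, drop = FALSE], dc,
                       n_negatives = loss_cfg$n_negatives)
      st <- layerwise_step(net, heads, k, lay, vb, loss_cfg,
                           states$stage[[k]], states$head[[k]])
      net <- st$net; heads <- st$heads
      states$stage[[k]] <- st$fb_stage; states$head[[k]] <- st$fb_head
      hist[[i]] <- tibble::tibble(stage = k, step = step, loss = st$loss)
    }
  }
  list(net = net, heads = heads, history = do.call(rbind, hist))
}

#' Randomized layer-wise SSL training
#'
#' Per batch, one encoder stage is drawn uniformly at random and only that
#' stage and its auxiliary head are updated; preceding stages are forwarded
#' at their current values.
#'
#' @inheritParams gll_train
#' @param steps Total update steps.
#' @return List: `net`, `heads`, `history` (tibble with `step`, `stage`,
#'   `loss`), `draws` (the drawn stage per step).
#' @export
rll_train <- function(net, heads = NULL, images, steps = 150L,
                      batch_size = 16L, deform_cfg = deformation_config(),
                      loss_cfg = hinge_config(), rule = "BP",
                      optimizer = "adam", lr = 1e-3, seed = 1L) {
  lay <- stage_layout(net)
  if (is.null(heads)) heads <- build_aux_heads(net, seed = seed)
  K <- length(lay$encoder_stages)
  states <- make_layerwise_states(K, rule, optimizer, lr)
  N <- dim(images)[4]
  seeds <- derive_seeds(seed, 3L * steps)
  hist <- vector("list", steps)
  draws <- integer(steps)
  for (step in seq_len(steps)) {
    k <- with_seed(seeds[3L * step - 2L], sample.int(K, 1L))
    draws[step] <- k
    idx <- with_seed(seeds[3L * step - 1L], sample_batch_idx(N, batch_size))
    dc <- deform_cfg; dc$seed <- seeds[3L * step]
    vb <- make_views(images[, , , idx, drop = FALSE], dc,
                     n_negatives = loss_cfg$n_negatives)
    st <- layerwise_step(net, heads, k, lay, vb, loss_cfg,
                         states$stage[[k]], states$head[[k]])
    net <- st$net; heads <- st$heads
    states$stage[[k]] <- st$fb_stage; states$head[[k]] <- st$fb_head
    hist[[step]] <- tibble::tibble(step = step, stage = k, loss = st$loss)
  }
  list(net = net, heads = heads, history = do.call(rbind, hist), draws = draws)
}
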