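# Single-step Difference Target Propagation with pooling forward stages and
# learned strided-deconvolution inverses.
#
# Forward stages f_l are the network's trainable stages (conv + following
# pooling/activation; the top stage is flatten + linear). Backward stages
# g_l, l = 2..L, approximate f_l^{-1}: a strided deconvolution for conv
# stages (realized as the adjoint of a strided convolution whose geometry is
# solved so that g_l's output shape equals f_l's input shape) and a plain
# linear map for the top stage. No stage update ever reads the forward
# weights of the layer above: credit flows only through targets.

# choose a conv geometry (kernel, stride, pad = 0 or 1) mapping the spatial
# size of the stage input to that of the stage output
solve_deconv_geom <- function(shape_in, shape_out) {
  H_in <- shape_in[2]; H_out <- shape_out[2]
  if (H_out == H_in) return(list(k = 3L, stride = 1L, pad = 1L))
  for (stride in 2:4) for (pad in 0:1) {
    k <- H_in + 2L * pad - stride * (H_out - 1L)
    if (k >= stride && k <= 4L && k >= 1L)
      return(list(k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad)))
  }
  contract_error("no strided-deconv geometry maps ", H_out, " back to ", H_in)
}

#' Build a DTP network
#'
#' Wraps a [build_network()] encoder with backward stages `g_l` for
#' `l = 2..L` and the DTP hyperparameters.
#'
#' @param config A [network_config()] ending in flatten + linear.
#' @param seed Integer seed (forward and inverse parameters).
#' @param eta_target Step size of the top target
#'   (`xhat_L = x_L - eta_target * dL/dx_L`).
#' @param lr_inverse Learning rate of the inverse (autoencoder) SGD steps.
#' @param lr_forward Learning rate of the forward stage updates.
#' @param optimizer Optimizer for the forward stages (`"sgd"` follows the
#'   single-step algorithm literally; `"adam"` is the as-in-paper variant
#'   for encoder training).
#' @return A `dtp_network`.
#' @export
dtp_network <- function(config, seed = 1L, eta_target = NULL,
                        lr_forward = 1e-3, lr_inverse = 1e-3,
                        optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  net <- build_network(config, seed)
  lay <- stage_layout(net)
  stages <- c(lay$encoder_stages, list(lay$head_stage))
  Ls <- length(stages)
  g <- vector("list", Ls)
  gseeds <- derive_seeds(seed + 1L, Ls)
  for (l in 2:Ls) {
    span <- stages[[l]]
    sh_in <- net$layers[[span[1]]]$shape_in
    sh_out <- net$layers[[span[length(span)]]]$shape_out
    has_conv <- any(vapply(span, function(i) net$layers[[i]]$spec$kind == "conv", logical(1)))
    if (has_conv) {
      geo <- solve_deconv_geom(sh_in, sh_out)
      gg <- conv_geom(sh_in[1], sh_in[2], sh_in[3], geo$k, geo$stride, geo$pad)
      if (gg$Ho != sh_out[2] || gg$Wo != sh_out[3])
        contract_error("deconv geometry mismatch at stage ", l)
      fan <- sh_out[1] * geo$k^2
      V <- with_seed(gseeds[l], matrix(runif(sh_out[1] * gg$patch_len,
                                             -1 / sqrt(fan), 1 / sqrt(fan)),
                                       sh_out[1], gg$patch_len))
      g[[l]] <- list(kind = "deconv", V = V, geom = gg)
    } else {
      d_in <- prod(sh_in); d_out <- prod(sh_out)
      V <- with_seed(gseeds[l], matrix(runif(d_in * d_out, -1 / sqrt(d_out),
                                             1 / sqrt(d_out)), d_in, d_out))
      g[[l]] <- list(kind = "linear", V = V)
    }
  }
  structure(list(net = net, stages = stages, g = g, L = Ls,
                 eta_target = eta_target %||% lr_forward,
                 lr_forward = lr_forward, lr_inverse = lr_inverse,
                 optimizer = optimizer,
                 fb = feedback_state("BP", optimizer, lr_forward)),
            class = "dtp_network")
}

# apply backward stage g_l to a stage-l output batch z (flat matrix)
g_apply <- function(gl, z) {
  if (gl$kind == "linear") return(gl$V %*% z)
  n <- ncol(z)
  Z2 <- matrix(z, nrow = nrow(gl$V))
  conv_input_grad(gl$V, Z2, gl$geom, n)
}

#' Forward pass of a DTP network
#'
#' Identical composition to [forward()] on the wrapped encoder; returns the
#' full activation trace plus per-stage outputs.
#'
#' @param dnet A `dtp_network`.
#' @param batch Image batch as in [forward()].
#' @return List: `trace` (the [forward()] trace), `stage_x` (list of stage
#'   outputs, `stage_x[[0 + 1]]` being the input), `n`.
#' @export
dtp_forward <- function(dnet, batch) {
  tr <- forward(dnet$net, batch)
  ends <- vapply(dnet$stages, function(s) s[length(s)], integer(1))
  stage_x <- c(list(tr$x0), lapply(ends, function(e) tr$x[[e]]))
  list(trace = tr, stage_x = stage_x, n = tr$n)
}

#' One SGD step on every inverse (layer-wise autoencoder)
#'
#' For `l = L..2` takes one SGD step on
#' `L_l^inv = mean_batch || g_l(f_l(x_{l-1})) - x_{l-1} ||_2^2`
#' at the inverse learning rate; forward parameters are untouched.
#'
#' @param dnet A `dtp_network`.
#' @param fwd A [dtp_forward()] result for the current batch.
#' @return List: `dnet` (updated inverses), `inverse_losses` (numeric, one
#'   per stage, NA for stage 1).
#' @export
train_inverses <- function(dnet, fwd) {
  n <- fwd$n
  losses <- rep(NA_real_, dnet$L)
  for (l in dnet$L:2) {
    x_prev <- fwd$stage_x[[l]]        # x_{l-1} (stage_x is 0-indexed shifted)
    x_l <- fwd$stage_x[[l + 1L]]
    gl <- dnet$g[[l]]
    rec <- g_apply(gl, x_l)
    resid <- rec - x_prev
    losses[l] <- sum(resid^2) / n
    r <- 2 * resid / n
    if (gl$kind == "linear") {
      dV <- tcrossprod(r, x_l)
    } else {
      Z2 <- matrix(x_l, nrow = nrow(gl$V))
      dV <- conv_weight_grad(Z2, conv_patches(r, gl$geom))
    }
    dnet$g[[l]]$V <- gl$V - dnet$lr_inverse * dV
  }
  list(dnet = dnet, inverse_losses = losses)
}

#' Difference-corrected target propagation
#'
#' Sets the top target `xhat_L = x_L - eta * dL/dx_L` and propagates
#' `xhat_{l-1} = x_{l-1} - g_l(x_l) + g_l(xhat_l)` down to stage 1.
#'
#' @param dnet A `dtp_network`.
#' @param fwd A [dtp_forward()] result.
#' @param top_gradient Matrix `(d_L, n)`: loss gradient w.r.t. the top
#'   stage output.
#' @param eta Top target step size; defaults to `dnet$eta_target`.
#' @return List of targets `xhat[[l]]`, `l = 1..L` (class `target_trace`).
#' @export
compute_targets <- function(dnet, fwd, top_gradient, eta = NULL) {
  eta <- eta %||% dnet$eta_target
  L <- dnet$L
  x_top <- fwd$stage_x[[L + 1L]]
  if (!all(dim(top_gradient) == dim(x_top)))
    contract_error("top_gradient shape does not match the top stage output")
  xhat <- vector("list", L)
  xhat[[L]] <- x_top - eta * top_gradient
  for (l in L:2) {
    x_prev <- fwd$stage_x[[l]]
    x_l <- fwd$stage_x[[l + 1L]]
    # difference correction x_{l-1} - g_l(x_l) + g_l(xhat_l), computed as
    # g_l(xhat_l - x_l) (identical for the linear g_l used here) so that a
    # zero top gradient gives targets bit-identical to the activations
    xhat[[l - 1L]] <- x_prev + g_apply(dnet$g[[l]], xhat[[l]] - x_l)
  }
  structure(xhat, class = "target_trace")
}

# gradient of the local loss mean_batch ||f_l(x_{l-1}) - xhat_l||^2 w.r.t.
# the stage's trainable weights, via the stage-internal chain only
stage_local_grad <- function(dnet, fwd, l, xhat_l) {
  span <- dnet$stages[[l]]
  tr <- fwd$trace
  n <- fwd$n
  x_l <- fwd$stage_x[[l + 1L]]
  d <- 2 * (x_l - xhat_l) / n
  for (i in rev(seq_along(span))) {
    ll <- span[i]
    ly <- dnet$net$layers[[ll]]
    d <- d * act_deriv(tr$h[[ll]], ly$spec$activation)
    if (ly$spec$kind == "conv") {
      D2 <- matrix(d, nrow = ly$spec$channels)
      return(list(layer = ll, grad = conv_weight_grad(D2, tr$cache[[ll]]$patches)))
    }
    if (ly$spec$kind == "linear") {
      x_prev <- if (ll == 1L) tr$x0 else tr$x[[ll - 1L]]
      return(list(layer = ll, grad = tcrossprod(d, x_prev)))
    }
    d <- switch(ly$spec$kind,
      maxpool = maxpool_backward(d, tr$cache[[ll]]$win, ly$geom, n),
      avgpool = avgpool_backward(d, ly$geom, n),
      flatten = d)
  }
  contract_error("stage ", l, " has no trainable layer")
}

#' One full DTP training step on a view batch
#'
#' Algorithm order: forward both branches; one SGD step per inverse; set and
#' propagate targets; one optimizer step per forward stage on its local loss
#' (the top stage on the global contrastive hinge loss). Updates of stage l
#' use only `x_{l-1}` and `xhat_l` — no transposed forward weights anywhere.
#'
#' @param dnet A `dtp_network`.
#' @param vb A `view_batch` with negative sets.
#' @param loss_cfg A [hinge_config()].
#' @return List: `dnet`, `loss` (global hinge loss), `inverse_losses`,
#'   `local_losses`.
#' @export
dtp_step <- function(dnet, vb, loss_cfg = hinge_config()) {
  if (is.null(vb$negatives)) contract_error("view batch has no negative sets")
  fwd_A <- dtp_forward(dnet, vb$view_A)
  fwd_B <- dtp_forward(dnet, vb$view_B)
  L <- dnet$L
  emb_A <- fwd_A$stage_x[[L + 1L]]
  emb_B <- fwd_B$stage_x[[L + 1L]]
  loss <- hinge_loss(emb_A, emb_B, vb$negatives, loss_cfg)
  err <- hinge_error_signals(emb_A, emb_B, vb$negatives, loss_cfg)
  err$blocked <- loss_cfg$block_gradient
  g <- branch_gradients(err)
  # inverses: one step per branch that receives targets
  ti <- train_inverses(dnet, fwd_B)
  dnet <- ti$dnet
  inv_losses <- ti$inverse_losses
  branches <- list(list(fwd = fwd_B, grad = g$grad_B / fwd_B$n))
  if (!loss_cfg$block_gradient && any(g$grad_A != 0))
    branches <- c(branches, list(list(fwd = fwd_A, grad = g$grad_A / fwd_A$n)))
  grads <- vector("list", dnet$net$L)
  local_losses <- rep(0, L)
  for (br in branches) {
    targets <- compute_targets(dnet, br$fwd, br$grad)
    for (l in seq_len(L - 1L)) {
      local_losses[l] <- local_losses[l] +
        sum((br$fwd$stage_x[[l + 1L]] - targets[[l]])^2) / br$fwd$n
      wg <- stage_local_grad(dnet, br$fwd, l, targets[[l]])
      grads[[wg$layer]] <- (grads[[wg$layer]] %||% 0) + wg$grad
    }
    # top stage: global-loss gradient, Hebbian in x_{L-1}
    span <- dnet$stages[[L]]
    top_l <- span[length(span)]
    x_prev <- if (top_l == 1L) br$fwd$trace$x0 else br$fwd$trace$x[[top_l - 1L]]
    grads[[top_l]] <- (grads[[top_l]] %||% 0) + tcrossprod(br$grad, x_prev)
  }
  local_losses[L] <- as.numeric(loss)
  st <- optimizer_step(dnet$net, grads, dnet$fb)
  dnet$net <- st$net; dnet$fb <- st$fb
  list(dnet = dnet, loss = as.numeric(loss), inverse_losses = inv_losses,
       local_losses = local_losses)
}

#' Train a DTP network with contrastive SSL
#'
#' @param dnet A `dtp_network`.
#' @param images Unlabeled images `(C, H, W, N)`.
#' @param steps,batch_size,deform_cfg,loss_cfg,seed As in [train_e2e()].
#' @return List: `dnet`, `history` (tibble: step, loss, mean inverse loss).
#' @export
dtp_train <- function(dnet, images, steps = 200L, batch_size = 16L,
                      deform_cfg = deformation_config(),
                      loss_cfg = hinge_config(), seed = 1L) {
  N <- dim(images)[4]
  seeds <- derive_seeds(seed, 2L * steps)
  hist <- vector("list", steps)
  for (step in seq_len(steps)) {
    idx <- with_seed(seeds[2L * step - 1L], sample_batch_idx(N, batch_size))
    dc <- deform_cfg; dc$seed <- seeds[2L * step]
    vb <- make_views(images[, , , idx, drop = FALSE], dc,
                     n_negatives = loss_cfg$n_negatives)
    st <- dtp_step(dnet, vb, loss_cfg)
    dnet <- st$dnet
    hist[[step]] <- tibble::tibble(step = step, loss = st$loss,
                                   inverse_loss = mean(st$inverse_losses, na.rm = TRUE))
  }
  list(dnet = dnet, history = do.call(rbind, hist))
}
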