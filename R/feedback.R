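# Interchangeable error-propagation rules and parameter updates.
#
# BP propagates errors through the transposed forward weights; RF substitutes
# fixed random feedback blocks B (stored in the transposed orientation of the
# forward map); URF uses the same feedback blocks but gives them the
# transposed increments of the forward weights, so that feedback initialized
# at the forward transpose reproduces BP exactly at every step.

#' Create a feedback/optimizer state
#'
#' @param rule Error-propagation rule: `"BP"`, `"RF"` or `"URF"`.
#' @param optimizer `"sgd"` (the plain reference rule matching the update
#'   equations) or `"adam"` (the variant used in the reference experiments).
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return A `feedback_state`.
#' @export
feedback_state <- function(rule = c("BP", "RF", "URF"),
                           optimizer = c("adam", "sgd"),
                           lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rule <- match.arg(rule)
  optimizer <- match.arg(optimizer)
  structure(list(rule = rule, optimizer = optimizer, lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 t = 0L, m = list(), v = list()),
            class = "feedback_state")
}

#' Per-layer error signals of a cached forward pass
#'
#' Propagates a top-layer error `delta_L` (with respect to the top
#' pre-activation) down the network: `delta_l = sigma'(h_l) * (M^T delta_{l+1})`
#' with `M = W_{l+1}` under BP and the feedback block under RF/URF. Max-pool
#' layers route the error to the recorded argmax; average pools spread it
#' uniformly; flatten is the identity.
#'
#' @param net A `plausnet_network`.
#' @param trace The [forward()] trace of the same net on the same batch.
#' @param top_delta Matrix `(d_L, n)`: loss gradient w.r.t. the top layer
#'   pre-activation.
#' @param fb A [feedback_state()] (only the rule matters here).
#' @return List with `deltas` (per trainable layer, in flat `(d_l, n)` form)
#'   and `grads` (per trainable layer, the loss gradient w.r.t. `W_l`).
#' @export
backward_errors <- function(net, trace, top_delta, fb = feedback_state("BP")) {
  stopifnot(inherits(net, "plausnet_network"), inherits(trace, "activation_trace"))
  n <- trace$n
  if (!is.matrix(top_delta) || ncol(top_delta) != n)
    contract_error("top_delta must be a (d_L, n) matrix")
  rule <- fb$rule
  deltas <- vector("list", net$L)
  grads <- vector("list", net$L)
  d <- top_delta
  for (l in net$L:1) {
    ly <- net$layers[[l]]
    kind <- ly$spec$kind
    if (kind %in% c("conv", "linear") && rule != "BP" && is.null(ly$B))
      contract_error("layer ", l, ": feedback block B missing under rule ", rule)
    x_prev <- if (l == 1L) trace$x0 else trace$x[[l - 1L]]
    g_in <- switch(kind,
      conv = {
        deltas[[l]] <- d
        D2 <- matrix(d, nrow = ly$spec$channels)
        grads[[l]] <- conv_weight_grad(D2, trace$cache[[l]]$patches)
        Weff <- if (rule == "BP") ly$W else t(ly$B)
        conv_input_grad(Weff, D2, ly$geom, n)
      },
      linear = {
        deltas[[l]] <- d
        grads[[l]] <- tcrossprod(d, x_prev)
        if (rule == "BP") crossprod(ly$W, d) else ly$B %*% d
      },
      maxpool = maxpool_backward(d, trace$cache[[l]]$win, ly$geom, n),
      avgpool = avgpool_backward(d, ly$geom, n),
      flatten = d)
    if (l > 1L) {
      prev <- net$layers[[l - 1L]]
      d <- g_in * act_deriv(trace$h[[l - 1L]], prev$spec$activation)
    }
  }
  list(deltas = deltas, grads = grads)
}

# One optimizer step on selected layers. grads: list indexed like net$layers
# (NULL entries are skipped) holding loss gradients dL/dW. Under URF the
# feedback block receives the transposed increment of its forward weights.
optimizer_step <- function(net, grads, fb) {
  fb$t <- fb$t + 1L
  for (l in seq_along(grads)) {
    g <- grads[[l]]
    if (is.null(g)) next
    if (!all(is.finite(g)))
      stop("non-finite update at layer ", l, call. = FALSE)
    if (fb$optimizer == "sgd") {
      step <- fb$lr * g
    } else {
      key <- as.character(l)
      m <- fb$m[[key]] %||% (g * 0)
      v <- fb$v[[key]] %||% (g * 0)
      m <- fb$beta1 * m + (1 - fb$beta1) * g
      v <- fb$beta2 * v + (1 - fb$beta2) * g^2
      fb$m[[key]] <- m; fb$v[[key]] <- v
      mh <- m / (1 - fb$beta1^fb$t)
      vh <- v / (1 - fb$beta2^fb$t)
      step <- fb$lr * mh / (sqrt(vh) + fb$eps)
    }
    net$layers[[l]]$W <- net$layers[[l]]$W - step
    if (fb$rule == "URF" && !is.null(net$layers[[l]]$B))
      net$layers[[l]]$B <- net$layers[[l]]$B - t(step)
  }
  list(net = net, fb = fb)
}

#' Apply accumulated updates to a network
#'
#' Decrements each trainable `W_l` by the configured optimizer's step on the
#' accumulated gradient `delta_l x_{l-1}^T`; under URF the feedback blocks
#' receive the same (transposed) increments.
#'
#' @param net A `plausnet_network`.
#' @param grads List of per-layer gradients as returned by
#'   [backward_errors()] (sum over branches before calling, if several).
#' @param fb A [feedback_state()]; returned updated (optimizer moments, step
#'   counter).
#' @return List with elements `net` and `fb`.
#' @export
apply_updates <- function(net, grads, fb) optimizer_step(net, grads, fb)

#' Alignment between feedback-rule and BP update directions
#'
#' Diagnostic for feedback alignment: the cosine between the per-layer weight
#' gradients computed under the given rule and under BP, for one batch.
#'
#' @param net A `plausnet_network`.
#' @param trace A [forward()] trace.
#' @param top_delta Top-layer error as in [backward_errors()].
#' @param fb A [feedback_state()] with rule RF or URF.
#' @return A tibble: `layer`, `rule`, `update_norm`, `bp_alignment`.
#' @export
feedback_alignment <- function(net, trace, top_delta, fb) {
  ref <- backward_errors(net, trace, top_delta, feedback_state("BP"))
  alt <- backward_errors(net, trace, top_delta, fb)
  rows <- list()
  for (l in seq_along(alt$grads)) {
    if (is.null(alt$grads[[l]])) next
    a <- as.vector(alt$grads[[l]]); b <- as.vector(ref$grads[[l]])
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = l, rule = fb$rule, update_norm = na,
      bp_alignment = if (na > 0 && nb > 0) sum(a * b) / (na * nb) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Set feedback blocks to the forward transpose
#'
#' Symmetric initialization: every `B_l` becomes `t(W_l)` (the BP-equivalent
#' configuration used by the RF symmetry limit and the URF-equals-BP
#' identity).
#'
#' @param net A `plausnet_network`.
#' @return The modified network.
#' @export
set_symmetric_feedback <- function(net) {
  for (l in seq_along(net$layers))
    if (!is.null(net$layers[[l]]$W)) net$layers[[l]]$B <- t(net$layers[[l]]$W)
  net
}
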