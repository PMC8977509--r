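# Low-level layer primitives.
#
# All feature maps are held as "flat matrices": a batch of n maps with shape
# (C, H, W) is a matrix of dim (C*H*W, n) whose within-column order is channel
# fastest, then row, then column (the natural flattening of an R array with
# dim c(C, H, W)). Convolutions are computed by im2col gathering followed by a
# single matrix product; the index maps are precomputed per layer geometry so
# forward and backward passes are pure gather/scatter plus BLAS.

#' Declare one network layer
#'
#' @param kind One of `"conv"`, `"linear"`, `"maxpool"`, `"avgpool"`,
#'   `"flatten"`.
#' @param activation Elementwise nonlinearity applied after the layer's
#'   operation: `"none"`, `"hardtanh"` (clamped to \[-1, 1\]) or `"tanh"`.
#' @param channels Output channels (conv) or output units (linear).
#' @param kernel Square kernel size in pixels (conv).
#' @param stride Stride in pixels (conv).
#' @param pool Pooling window and stride in pixels (maxpool/avgpool).
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind = c("conv", "linear", "maxpool", "avgpool", "flatten"),
                       activation = c("none", "hardtanh", "tanh"),
                       channels = NULL, kernel = 3L, stride = 1L, pool = 2L) {
  kind <- match.arg(kind)
  activation <- match.arg(activation)
  if (kind == "conv") {
    if (is.null(channels)) contract_error("conv layer needs `channels`")
    if (kernel < 1 || stride < 1) contract_error("conv kernel and stride must be >= 1")
  }
  if (kind == "linear" && is.null(channels))
    contract_error("linear layer needs `channels` (output units)")
  if (kind %in% c("maxpool", "avgpool") && pool < 1)
    contract_error("pool size must be >= 1")
  structure(list(kind = kind, activation = activation,
                 channels = if (!is.null(channels)) as.integer(channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pool = as.integer(pool)),
            class = "layer_spec")
}

# Activation functions and derivatives w.r.t. the pre-activation.
act_fun <- function(h, activation) {
  switch(activation,
         none = h,
         hardtanh = pmin(pmax(h, -1), 1),
         tanh = tanh(h))
}

act_deriv <- function(h, activation) {
  switch(activation,
         none = array(1, dim = dim(h) %||% length(h)),
         hardtanh = (h > -1 & h < 1) * 1,
         tanh = 1 - tanh(h)^2)
}

# Geometry of a convolution: precomputed im2col index map.
# Patch-internal order is channel fastest, then kernel row, then kernel col;
# output positions are ordered row fastest, then col.
conv_geom <- function(C, H, W, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  if (Hp < k || Wp < k)
    contract_error("kernel ", k, " larger than padded input ", Hp, "x", Wp)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  off <- expand.grid(c = seq_len(C), dr = seq_len(k), dc = seq_len(k))
  pos <- expand.grid(io = seq_len(Ho), jo = seq_len(Wo))
  r  <- outer(off$dr, (pos$io - 1L) * stride, `+`)     # (C*k*k, Ho*Wo)
  cc <- outer(off$dc, (pos$jo - 1L) * stride, `+`)
  P <- off$c + C * ((r - 1L) + Hp * (cc - 1L))
  # positions of the original (unpadded) pixels inside the padded flat vector
  og <- expand.grid(c = seq_len(C), r = seq_len(H), cl = seq_len(W))
  pad_idx <- og$c + C * ((og$r + pad - 1L) + Hp * (og$cl + pad - 1L))
  list(C = C, H = H, W = W, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       P = P, Pvec = as.vector(P), grp = as.vector(P), pad_idx = pad_idx,
       d_in = C * H * W, d_out_spatial = Ho * Wo, patch_len = C * k * k)
}

# im2col: X is (C*H*W, n); returns (C*k*k, Ho*Wo*n)
conv_patches <- function(X, g) {
  n <- ncol(X)
  if (g$pad > 0L) {
    Xp <- matrix(0, g$C * g$Hp * g$Wp, n)
    Xp[g$pad_idx, ] <- X
  } else Xp <- X
  Pm <- Xp[g$Pvec, , drop = FALSE]            # (patch_len * Ho*Wo, n)
  dim(Pm) <- c(g$patch_len, g$d_out_spatial * n)
  Pm
}

# forward: weight Wm is (C_out, C*k*k); returns flat (C_out*Ho*Wo, n)
conv_forward <- function(Wm, patches, g, n) {
  Y <- Wm %*% patches                          # (C_out, Ho*Wo*n)
  dim(Y) <- c(nrow(Wm) * g$d_out_spatial, n)
  Y
}

# gradient w.r.t. the layer input, given dY as (C_out, Ho*Wo*n).
# Weff plays the role of the forward weight; passing t(B) substitutes the
# feedback matrix for the transposed forward map (random-feedback rules).
conv_input_grad <- function(Weff, dY, g, n) {
  dP <- crossprod(Weff, dY)                    # (patch_len, Ho*Wo*n)
  dim(dP) <- c(g$patch_len * g$d_out_spatial, n)
  rs <- rowsum(dP, group = g$grp)              # scatter-add into padded flat
  dXp <- matrix(0, g$C * g$Hp * g$Wp, n)
  dXp[as.integer(rownames(rs)), ] <- rs
  dXp[g$pad_idx, , drop = FALSE]
}

# gradient w.r.t. the weights: dY (C_out, Ho*Wo*n), patches (C*k*k, Ho*Wo*n)
conv_weight_grad <- function(dY, patches) tcrossprod(dY, patches)

# Pooling geometry: non-overlapping window of size q (stride q), no padding.
# Output flat order matches the input convention (channel fastest).
pool_geom <- function(C, H, W, q) {
  Ho <- (H - q) %/% q + 1L
  Wo <- (W - q) %/% q + 1L
  if (Ho < 1L || Wo < 1L) contract_error("pool window ", q, " larger than input")
  off <- expand.grid(dr = seq_len(q), dc = seq_len(q))
  pos <- expand.grid(c = seq_len(C), io = seq_len(Ho), jo = seq_len(Wo))
  r  <- outer(off$dr, (pos$io - 1L) * q, `+`)   # (q*q, U)
  cc <- outer(off$dc, (pos$jo - 1L) * q, `+`)
  Q <- matrix(rep(pos$c, each = q * q), q * q, nrow(pos)) +
    C * ((r - 1L) + H * (cc - 1L))
  list(C = C, H = H, W = W, q = q, Ho = Ho, Wo = Wo,
       Q = Q, Qvec = as.vector(Q), U = nrow(pos), d_in = C * H * W)
}

# Max pooling; ties broken by the first (row-major within window) index so
# traces are deterministic. Returns values and the winning input indices.
maxpool_forward <- function(X, g) {
  n <- ncol(X)
  G <- X[g$Qvec, , drop = FALSE]
  dim(G) <- c(g$q^2, g$U * n)
  tG <- t(G)
  am <- max.col(tG, ties.method = "first")
  vals <- tG[cbind(seq_along(am), am)]
  Y <- matrix(vals, g$U, n)
  win <- matrix(g$Q[cbind(am, rep(seq_len(g$U), times = n))], g$U, n)
  list(Y = Y, win = win)
}

maxpool_backward <- function(dY, win, g, n) {
  dX <- matrix(0, g$d_in, n)
  dX[as.vector(win) + (rep(seq_len(n), each = g$U) - 1L) * g$d_in] <- as.vector(dY)
  dX
}

avgpool_forward <- function(X, g) {
  n <- ncol(X)
  G <- X[g$Qvec, , drop = FALSE]
  dim(G) <- c(g$q^2, g$U * n)
  Y <- matrix(colMeans(G), g$U, n)
  Y
}

avgpool_backward <- function(dY, g, n) {
  dX <- matrix(0, g$d_in, n)
  spread <- as.vector(dY) / (g$q^2)
  idx <- rep(g$Qvec, times = n) +
    (rep(seq_len(n), each = g$q^2 * g$U) - 1L) * g$d_in
  # non-overlapping windows: every target index occurs exactly once
  dX[idx] <- rep(spread, each = g$q^2)
  dX
}
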