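# Network assembly and the forward pass.

#' Declare a network configuration
#'
#' @param input_shape Integer vector `c(channels, height, width)` of the
#'   images the network accepts, values scaled to \[0, 1\].
#' @param layers List of [layer_spec()] objects, bottom to top.
#' @param name Optional config name recorded in checkpoints.
#' @return A `network_config` object with per-layer shape bookkeeping.
#' @details Convolutions use "same"-style zero padding of `(kernel - 1) %/% 2`
#'   so that spatial size is preserved at stride 1 and only pooling layers
#'   downsample. Pooling uses non-overlapping windows (stride = window);
#'   trailing rows/columns that do not fill a window are dropped.
#' @export
network_config <- function(input_shape, layers, name = "custom") {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  input_shape <- as.integer(input_shape)
  shapes <- vector("list", length(layers) + 1L)
  shapes[[1L]] <- input_shape
  cur <- input_shape   # c(C, H, W); after flatten: c(d)
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (!inherits(ly, "layer_spec")) contract_error("layers[[", l, "]] is not a layer_spec")
    flat <- length(cur) == 1L
    cur <- switch(ly$kind,
      conv = {
        if (flat) contract_error("layer ", l, " (conv) follows a flattened layer ", l - 1L)
        pad <- (ly$kernel - 1L) %/% 2L
        Hp <- cur[2] + 2L * pad; Wp <- cur[3] + 2L * pad
        if (Hp < ly$kernel || Wp < ly$kernel)
          contract_error("layer ", l, " kernel exceeds input from layer ", l - 1L)
        c(ly$channels,
          (Hp - ly$kernel) %/% ly$stride + 1L,
          (Wp - ly$kernel) %/% ly$stride + 1L)
      },
      maxpool = ,
      avgpool = {
        if (flat) contract_error("layer ", l, " (pool) follows a flattened layer ", l - 1L)
        if (cur[2] < ly$pool || cur[3] < ly$pool)
          contract_error("layer ", l, " pool window exceeds input from layer ", l - 1L)
        c(cur[1], cur[2] %/% ly$pool, cur[3] %/% ly$pool)
      },
      flatten = prod(cur),
      linear = {
        d_in <- prod(cur)
        ly$channels
      })
    shapes[[l + 1L]] <- as.integer(cur)
  }
  structure(list(input_shape = input_shape, layers = layers,
                 shapes = shapes, name = name),
            class = "network_config")
}

#' Encoder + projection head used for 32x32 RGB experiments
#'
#' Five 3x3 stride-1 convolutions (32, 32, 64, 64, 512 channels) with
#' hardtanh nonlinearities and three 2x2 max-pools, followed by a flatten and
#' a 64-unit linear projection head: six trainable parameter blocks in total.
#' @param embedding_dim Projection head width.
#' @return A `network_config`.
#' @export
config_cifar_encoder <- function(embedding_dim = 64L) {
  network_config(c(3L, 32L, 32L), list(
    layer_spec("conv", channels = 32, activation = "hardtanh"),
    layer_spec("conv", channels = 32),
    layer_spec("maxpool"),
    layer_spec("conv", channels = 64, activation = "hardtanh"),
    layer_spec("conv", channels = 64),
    layer_spec("maxpool"),
    layer_spec("conv", channels = 512),
    layer_spec("maxpool"),
    layer_spec("flatten"),
    layer_spec("linear", channels = embedding_dim)
  ), name = "cifar-encoder")
}

#' Shallow encoder + projection head for 28x28 grayscale experiments
#'
#' Three 3x3 convolutions (32, 64, 128 channels), each followed by a 2x2
#' max-pool and tanh, then flatten and a 64-unit linear head.
#' @param embedding_dim Projection head width.
#' @param channels Convolution channel counts (length 3).
#' @return A `network_config`.
#' @export
config_mnist_encoder <- function(embedding_dim = 64L, channels = c(32L, 64L, 128L)) {
  stopifnot(length(channels) == 3)
  network_config(c(1L, 28L, 28L), list(
    layer_spec("conv", channels = channels[1]),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("conv", channels = channels[2]),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("conv", channels = channels[3]),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("flatten"),
    layer_spec("linear", channels = embedding_dim)
  ), name = "mnist-encoder")
}

#' Approximate VGG6-style encoder for 96x96 RGB inputs (64x64 crops)
#'
#' A best-effort six-convolution VGG-like stack; the exact composition used
#' in prior work is not printed anywhere we implement from, so this config is
#' labeled approximate and is not exercised by the test suite.
#' @param embedding_dim Projection head width.
#' @return A `network_config`.
#' @export
config_vgg6_approx <- function(embedding_dim = 64L) {
  network_config(c(3L, 64L, 64L), list(
    layer_spec("conv", channels = 64, activation = "hardtanh"),
    layer_spec("conv", channels = 64),
    layer_spec("maxpool", activation = "hardtanh"),
    layer_spec("conv", channels = 128, activation = "hardtanh"),
    layer_spec("conv", channels = 128),
    layer_spec("maxpool", activation = "hardtanh"),
    layer_spec("conv", channels = 256, activation = "hardtanh"),
    layer_spec("conv", channels = 256),
    layer_spec("maxpool", activation = "hardtanh"),
    layer_spec("avgpool"),
    layer_spec("flatten"),
    layer_spec("linear", channels = embedding_dim)
  ), name = "vgg6-approx")
}

trainable_kind <- function(kind) kind %in% c("conv", "linear")

#' Build a network from a configuration
#'
#' Forward weights are drawn uniformly in +/- 1/sqrt(fan-in); feedback blocks
#' `B` (used by the random-feedback rules) are drawn independently from the
#' same scheme and stored in the transposed orientation of the layer's
#' linearized forward map. No biases are used: each trainable layer computes
#' `h = W x`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed; the build is reproducible from it.
#' @return A `plausnet_network`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  layers <- vector("list", length(config$layers))
  with_seed(seed, {
    for (l in seq_along(config$layers)) {
      sp <- config$layers[[l]]
      s_in <- config$shapes[[l]]
      s_out <- config$shapes[[l + 1L]]
      ly <- list(spec = sp, shape_in = s_in, shape_out = s_out)
      if (sp$kind == "conv") {
        pad <- (sp$kernel - 1L) %/% 2L
        ly$geom <- conv_geom(s_in[1], s_in[2], s_in[3], sp$kernel, sp$stride, pad)
        fan_in <- s_in[1] * sp$kernel^2
        bnd <- 1 / sqrt(fan_in)
        ly$W <- matrix(runif(sp$channels * fan_in, -bnd, bnd), sp$channels, fan_in)
        ly$B <- matrix(runif(fan_in * sp$channels, -bnd, bnd), fan_in, sp$channels)
      } else if (sp$kind == "linear") {
        d_in <- prod(s_in)
        bnd <- 1 / sqrt(d_in)
        ly$W <- matrix(runif(sp$channels * d_in, -bnd, bnd), sp$channels, d_in)
        ly$B <- matrix(runif(d_in * sp$channels, -bnd, bnd), d_in, sp$channels)
      } else if (sp$kind %in% c("maxpool", "avgpool")) {
        ly$geom <- pool_geom(s_in[1], s_in[2], s_in[3], sp$pool)
      }
      layers[[l]] <- ly
    }
  })
  structure(list(config = config, layers = layers, L = length(layers),
                 seed = as.integer(seed)),
            class = "plausnet_network")
}

#' @export
print.plausnet_network <- function(x, ...) {
  cat("<plausnet_network> config:", x$config$name,
      " input:", paste(x$config$input_shape, collapse = "x"), "\n")
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  %2d %-8s act=%-8s out=%s%s\n", l, ly$spec$kind, ly$spec$activation,
                paste(ly$shape_out, collapse = "x"),
                if (!is.null(ly$W)) sprintf("  W[%dx%d]", nrow(ly$W), ncol(ly$W)) else ""))
  }
  invisible(x)
}

# Coerce an image batch, array (C,H,W,n) or (C,H,W), to a flat matrix (CHW, n)
as_flat_batch <- function(batch, input_shape) {
  if (is.matrix(batch)) {
    if (nrow(batch) != prod(input_shape))
      contract_error("batch rows ", nrow(batch), " != input size ", prod(input_shape))
    return(batch)
  }
  d <- dim(batch)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    contract_error("batch must be an array (C,H,W[,n]) or a flat matrix")
  if (length(d) == 3L) d <- c(d, 1L)
  if (!all(d[1:3] == input_shape))
    contract_error("batch spatial size ", paste(d[1:3], collapse = "x"),
                   " does not match config input ", paste(input_shape, collapse = "x"))
  matrix(batch, prod(d[1:3]), d[4])
}

#' Forward pass with activation caching
#'
#' Computes `h_l = op_l(x_{l-1})`, `x_l = sigma_l(h_l)` for every layer and
#' caches what the backward passes need (im2col patches for convolutions,
#' winning indices for max-pools). The top layer of a standard config is a
#' linear head with no nonlinearity, so `x_L = h_L`.
#'
#' @param net A `plausnet_network`.
#' @param batch Image batch: array `(C, H, W, n)` or flat matrix `(C*H*W, n)`.
#' @return An `activation_trace` with elements `x0`, `h`, `x`, `cache`, `n`.
#' @export
forward <- function(net, batch) {
  stopifnot(inherits(net, "plausnet_network"))
  X <- as_flat_batch(batch, net$config$input_shape)
  n <- ncol(X)
  h <- vector("list", net$L); x <- vector("list", net$L); cache <- vector("list", net$L)
  cur <- X
  for (l in seq_len(net$L)) {
    ly <- net$layers[[l]]
    hl <- switch(ly$spec$kind,
      conv = {
        p <- conv_patches(cur, ly$geom)
        cache[[l]] <- list(patches = p)
        conv_forward(ly$W, p, ly$geom, n)
      },
      linear = ly$W %*% cur,
      maxpool = {
        mp <- maxpool_forward(cur, ly$geom)
        cache[[l]] <- list(win = mp$win)
        mp$Y
      },
      avgpool = avgpool_forward(cur, ly$geom),
      flatten = cur)
    if (!all(is.finite(hl)))
      stop("non-finite activations at layer ", l, call. = FALSE)
    xl <- act_fun(hl, ly$spec$activation)
    h[[l]] <- hl; x[[l]] <- xl
    cur <- xl
  }
  structure(list(x0 = X, h = h, x = x, cache = cache, n = n),
            class = "activation_trace")
}

#' Embed a batch of images
#'
#' @param net A `plausnet_network` whose config ends in flatten + linear.
#' @param batch Image batch as in [forward()].
#' @param strip_head If `TRUE`, return the flattened output of the last
#'   convolutional block (the linear-evaluation feature); otherwise the
#'   projection-head output.
#' @param layer Optional layer index: return the flattened activations of
#'   that layer instead (per-layer probe curves loop over this).
#' @return A matrix `(dim, n)`, one column per image.
#' @export
embed <- function(net, batch, strip_head = FALSE, layer = NULL) {
  tr <- forward(net, batch)
  if (!is.null(layer)) {
    if (layer < 1L || layer > net$L) contract_error("layer out of range")
    x <- tr$x[[layer]]
    return(matrix(x, nrow = prod(net$layers[[layer]]$shape_out)))
  }
  if (!strip_head) return(tr$x[[net$L]])
  kinds <- vapply(net$layers, function(l) l$spec$kind, character(1))
  fl <- which(kinds == "flatten")
  if (length(fl) == 0) contract_error("config has no flatten layer; cannot strip head")
  tr$x[[max(fl)]]
}

#' Save a network checkpoint
#'
#' Writes all parameter blocks to `<path>.rds` and a JSON manifest
#' (layer specs, shapes, seed, provenance) to `<path>.json`.
#'
#' @param net A `plausnet_network`.
#' @param path Path prefix (without extension).
#' @param provenance Optional named list recorded in the manifest.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, provenance = list()) {
  params <- lapply(net$layers, function(l) list(W = l$W, B = l$B))
  saveRDS(list(params = params, seed = net$seed), paste0(path, ".rds"))
  manifest <- list(
    config_name = net$config$name,
    input_shape = net$config$input_shape,
    layers = lapply(net$config$layers, unclass),
    seed = net$seed,
    provenance = provenance)
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path Path prefix used in [save_checkpoint()].
#' @return A `plausnet_network` with the saved parameters.
#' @export
load_checkpoint <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"))
  specs <- lapply(man$layers, function(s)
    layer_spec(s$kind, s$activation,
               channels = if (!is.null(s$channels)) s$channels,
               kernel = s$kernel %||% 3L, stride = s$stride %||% 1L,
               pool = s$pool %||% 2L))
  cfg <- network_config(unlist(man$input_shape), specs, name = man$config_name %||% "loaded")
  blob <- readRDS(paste0(path, ".rds"))
  net <- build_network(cfg, seed = blob$seed %||% 1L)
  for (l in seq_along(net$layers)) {
    if (!is.null(blob$params[[l]]$W)) net$layers[[l]]$W <- blob$params[[l]]$W
    if (!is.null(blob$params[[l]]$B)) net$layers[[l]]$B <- blob$params[[l]]$B
  }
  net
}
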