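# Shared fixtures and independent straight-line oracles used across tests.
# Oracles deliberately use naive loops / direct formula transcription, never
# the package's vectorized code paths.

tiny_config <- function(channels = c(3L, 5L), input = c(1L, 8L, 8L),
                        embedding = 10L) {
  network_config(input, list(
    layer_spec("conv", channels = channels[1]),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("conv", channels = channels[2]),
    layer_spec("maxpool", activation = "tanh"),
    layer_spec("flatten"),
    layer_spec("linear", channels = embedding)
  ), name = "tiny-test")
}

mlp_config <- function(input = c(1L, 4L, 4L), hidden = 12L, out = 6L,
                       act = "tanh") {
  network_config(input, list(
    layer_spec("flatten"),
    layer_spec("linear", channels = hidden, activation = act),
    layer_spec("linear", channels = out)
  ), name = "mlp-test")
}

random_batch <- function(shape, n, seed = 1) {
  withr::with_seed(seed, array(runif(prod(shape) * n), c(shape, n)))
}

# naive sliding-window convolution: weight (C_out, C_in*k*k), patch order
# channel fastest then kernel row then kernel col; zero padding
conv_oracle <- function(x, W, k, stride, pad) {
  d <- dim(x); C <- d[1]; H <- d[2]; Wd <- d[3]; n <- d[4]
  C_out <- nrow(W)
  Hp <- H + 2 * pad; Wp <- Wd + 2 * pad
  Ho <- (Hp - k) %/% stride + 1; Wo <- (Wp - k) %/% stride + 1
  xp <- array(0, c(C, Hp, Wp, n))
  xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- x
  out <- array(0, c(C_out, Ho, Wo, n))
  for (smp in seq_len(n)) for (co in seq_len(C_out))
    for (io in seq_len(Ho)) for (jo in seq_len(Wo)) {
      acc <- 0
      for (c in seq_len(C)) for (dr in seq_len(k)) for (dc in seq_len(k)) {
        wi <- c + C * ((dr - 1) + k * (dc - 1))
        acc <- acc + W[co, wi] * xp[c, (io - 1) * stride + dr, (jo - 1) * stride + dc, smp]
      }
      out[co, io, jo, smp] <- acc
    }
  out
}

# naive non-overlapping max pool (first-index ties irrelevant for values)
maxpool_oracle <- function(x, q) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; n <- d[4]
  Ho <- H %/% q; Wo <- W %/% q
  out <- array(0, c(C, Ho, Wo, n))
  for (smp in seq_len(n)) for (c in seq_len(C))
    for (io in seq_len(Ho)) for (jo in seq_len(Wo))
      out[c, io, jo, smp] <- max(x[c, (io - 1) * q + seq_len(q),
                                   (jo - 1) * q + seq_len(q), smp])
  out
}

# straight-line transcription of the symmetric contrastive cross-entropy
simclr_oracle <- function(A, B, tau) {
  n <- ncol(A)
  sim <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  loss <- 0
  for (s in seq_len(n)) {
    den <- 0
    for (t in seq_len(n)) if (t != s) den <- den + exp(sim(A[, s], A[, t]) / tau)
    for (t in seq_len(n)) den <- den + exp(sim(A[, s], B[, t]) / tau)
    loss <- loss - log(exp(sim(A[, s], B[, s]) / tau) / den)
    den <- 0
    for (t in seq_len(n)) if (t != s) den <- den + exp(sim(B[, s], B[, t]) / tau)
    for (t in seq_len(n)) den <- den + exp(sim(B[, s], A[, t]) / tau)
    loss <- loss - log(exp(sim(B[, s], A[, s]) / tau) / den)
  }
  loss
}

# small labeled fixture shared by evaluation tests
small_synth <- function(ipc = 30, seed = 7)
  generate_synthetic(synthetic_spec(images_per_class = ipc, seed = seed))

# deformation preset used for grayscale training in tests
gray_deform <- function(seed = 1L)
  deformation_config(crop_scale_range = c(0.5, 1), flip_prob = 0.5,
                     jitter_strengths = c(0.4, 0.4, 0, 0),
                     grayscale_prob = 0, seed = seed)
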