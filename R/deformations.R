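# Random image deformations: positive-pair view generation and test-set
# perturbations. Geometry (resized crop, flip, affine) is realized on one
# inverse-map bilinear sampler with zero fill, so conventions are identical
# across all deformation families; photometric jitter is plain arithmetic on
# [0,1] channel values.

#' Configuration of the random view deformations
#'
#' Defaults follow the common contrastive-pretraining convention: random
#' resized crop with area scale in \[0.2, 1\], horizontal flip with
#' probability 0.5, color jitter strengths 0.4/0.4/0.4/0.1 (brightness,
#' contrast, saturation, hue) and random grayscale with probability 0.1.
#' Saturation/hue/grayscale only act on 3-channel images.
#'
#' @param crop_size Output side length in pixels; `NULL` keeps the input size.
#' @param crop_scale_range Area fraction interval of the random crop, in (0,1].
#' @param aspect_range Aspect-ratio interval of the random crop.
#' @param flip_prob Probability of a horizontal flip.
#' @param jitter_strengths Named or positional numeric of length 4:
#'   brightness, contrast, saturation, hue (hue as a fraction of a full turn).
#' @param jitter_prob Probability that color jitter is applied at all.
#' @param grayscale_prob Probability of conversion to grayscale.
#' @param seed Integer seed making every draw reproducible.
#' @return A `deformation_config`.
#' @export
deformation_config <- function(crop_size = NULL,
                               crop_scale_range = c(0.2, 1),
                               aspect_range = c(3 / 4, 4 / 3),
                               flip_prob = 0.5,
                               jitter_strengths = c(brightness = 0.4, contrast = 0.4,
                                                    saturation = 0.4, hue = 0.1),
                               jitter_prob = 0.8,
                               grayscale_prob = 0.1,
                               seed = 1L) {
  stopifnot(length(crop_scale_range) == 2, crop_scale_range[1] > 0,
            crop_scale_range[2] <= 1, diff(crop_scale_range) >= 0)
  for (p in c(flip_prob, jitter_prob, grayscale_prob))
    if (p < 0 || p > 1) contract_error("probabilities must lie in [0,1]")
  js <- rep_len(as.numeric(jitter_strengths), 4)
  names(js) <- c("brightness", "contrast", "saturation", "hue")
  structure(list(crop_size = if (!is.null(crop_size)) as.integer(crop_size),
                 crop_scale_range = crop_scale_range,
                 aspect_range = aspect_range,
                 flip_prob = flip_prob, jitter_strengths = js,
                 jitter_prob = jitter_prob,
                 grayscale_prob = grayscale_prob, seed = as.integer(seed)),
            class = "deformation_config")
}

#' Configuration of a random affine test-set deformation
#'
#' Used by the robustness protocol: rotation, translation and shear drawn
#' uniformly in symmetric ranges, zero fill outside the source image.
#' Defaults: rotation +/- 25 degrees, translation +/- 15% of the side,
#' shear +/- 10 degrees.
#'
#' @param max_rotation Degrees.
#' @param max_translate Fraction of the image side, per axis.
#' @param max_shear Degrees.
#' @param seed Integer seed.
#' @return An `affine_config`.
#' @export
affine_config <- function(max_rotation = 25, max_translate = 0.15,
                          max_shear = 10, seed = 1L) {
  structure(list(max_rotation = max_rotation, max_translate = max_translate,
                 max_shear = max_shear, seed = as.integer(seed)),
            class = "affine_config")
}

# Bilinear sampling of one image at fractional source coordinates.
# img: array (C, H, W); src_r, src_c: vectors of length U (output pixels,
# row fastest). Out-of-range samples use fill. Returns a (C, U) matrix.
bilinear_warp <- function(img, src_r, src_c, fill = 0) {
  d <- dim(img); C <- d[1]; H <- d[2]; W <- d[3]
  M <- matrix(img, C, H * W)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  U <- length(src_r)
  out <- matrix(fill, C, U)
  gather <- function(r, cc, w) {
    ok <- r >= 1 & r <= H & cc >= 1 & cc <= W & w > 0
    if (!any(ok)) return(NULL)
    idx <- (r[ok] - 1) + H * (cc[ok] - 1) + 1
    V <- M[, idx, drop = FALSE]
    list(ok = ok, contrib = V * rep(w[ok], each = C))
  }
  acc <- matrix(0, C, U)
  wmat <- list(list(r0,     c0,     (1 - fr) * (1 - fc)),
               list(r0 + 1, c0,     fr * (1 - fc)),
               list(r0,     c0 + 1, (1 - fr) * fc),
               list(r0 + 1, c0 + 1, fr * fc))
  wsum <- numeric(U)
  for (g in wmat) {
    gt <- gather(g[[1]], g[[2]], g[[3]])
    if (!is.null(gt)) {
      acc[, gt$ok] <- acc[, gt$ok] + gt$contrib
      wsum[gt$ok] <- wsum[gt$ok] + g[[3]][gt$ok]
    }
  }
  # missing weight mass corresponds to out-of-image neighbors -> fill
  acc + outer(rep(fill, C), 1 - wsum)
}

# Linear source grid of a crop [r and c handled identically]: crop of length
# len starting at origin (0-based), resized to out points. align-corners
# convention so that a full-size crop is the identity map.
crop_grid <- function(origin, len, out) {
  if (out == 1L) return(origin + (len + 1) / 2)
  origin + 1 + (seq_len(out) - 1) * (len - 1) / (out - 1)
}

deform_one <- function(img, cfg, out_size) {
  d <- dim(img); C <- d[1]; H <- d[2]; W <- d[3]
  Ho <- out_size; Wo <- out_size
  # random resized crop
  a <- runif(1, cfg$crop_scale_range[1], cfg$crop_scale_range[2])
  ar <- exp(runif(1, log(cfg$aspect_range[1]), log(cfg$aspect_range[2])))
  hc <- min(H, max(1, round(sqrt(a * H * W / ar))))
  wc <- min(W, max(1, round(sqrt(a * H * W * ar))))
  y0 <- if (H > hc) sample.int(H - hc + 1L, 1L) - 1L else 0L
  x0 <- if (W > wc) sample.int(W - wc + 1L, 1L) - 1L else 0L
  gr <- crop_grid(y0, hc, Ho)
  gc <- crop_grid(x0, wc, Wo)
  src_r <- rep(gr, times = Wo)
  src_c <- rep(gc, each = Ho)
  out <- bilinear_warp(img, src_r, src_c)
  dim(out) <- c(C, Ho, Wo)
  # horizontal flip
  if (runif(1) < cfg$flip_prob) out <- out[, , rev(seq_len(Wo)), drop = FALSE]
  # color jitter (random order would add nothing at these strengths; fixed order)
  if (runif(1) < cfg$jitter_prob) {
    js <- cfg$jitter_strengths
    if (js["brightness"] > 0) {
      f <- runif(1, max(0, 1 - js["brightness"]), 1 + js["brightness"])
      out <- out * f
    }
    if (js["contrast"] > 0) {
      f <- runif(1, max(0, 1 - js["contrast"]), 1 + js["contrast"])
      m <- mean(out)
      out <- (out - m) * f + m
    }
    if (C == 3L) {
      if (js["saturation"] > 0) {
        f <- runif(1, max(0, 1 - js["saturation"]), 1 + js["saturation"])
        gray <- (out[1, , ] + out[2, , ] + out[3, , ]) / 3
        for (ch in 1:3) out[ch, , ] <- gray + (out[ch, , ] - gray) * f
      }
      if (js["hue"] > 0) {
        dh <- runif(1, -js["hue"], js["hue"])
        out <- shift_hue(out, dh)
      }
    }
  }
  if (C == 3L && runif(1) < cfg$grayscale_prob) {
    gray <- (out[1, , ] + out[2, , ] + out[3, , ]) / 3
    for (ch in 1:3) out[ch, , ] <- gray
  }
  pmin(pmax(out, 0), 1)
}

# hue rotation of an RGB array (3, H, W); dh is a fraction of a full turn
shift_hue <- function(img, dh) {
  d <- dim(img)
  rgb <- matrix(pmin(pmax(img, 0), 1), 3, d[2] * d[3])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + dh) %% 1
  h6 <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h6) %% 6; f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  out <- rbind(
    ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p, ifelse(i == 3, p, ifelse(i == 4, t, v))))),
    ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v, ifelse(i == 3, q, ifelse(i == 4, p, p))))),
    ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t, ifelse(i == 3, v, ifelse(i == 4, v, q))))))
  array(out, d)
}

#' Select temporal-window negatives for one anchor
#'
#' Negatives are the `T` batch indices cyclically following the anchor,
#' modeling the temporally closest other observations; the anchor itself is
#' excluded.
#'
#' @param n Batch size.
#' @param T Number of negatives, `1 <= T <= n - 1`.
#' @param anchor Anchor index (1-based).
#' @return Integer vector of `T` indices.
#' @export
select_negatives <- function(n, T, anchor) {
  n <- as.integer(n); T <- as.integer(T); anchor <- as.integer(anchor)
  if (T < 1L || T > n - 1L)
    contract_error("need 1 <= T <= n-1 (got T=", T, ", n=", n, ")")
  if (anchor < 1L || anchor > n) contract_error("anchor out of range")
  ((anchor - 1L + seq_len(T)) %% n) + 1L
}

#' Create a pair of deformed views plus negative index sets
#'
#' Applies two independent draws of the configured random deformations to
#' every image, producing the A branch (anchors) and the B branch (positives;
#' negatives for other anchors are taken from this deformed B branch).
#'
#' @param batch Image batch, array `(C, H, W, n)` with values in \[0, 1\].
#' @param cfg A [deformation_config()].
#' @param n_negatives Negatives per anchor (`T`); `NULL` for none.
#' @param labels Optional labels carried through unchanged.
#' @return A `view_batch`: list with `view_A`, `view_B` (arrays
#'   `(C, crop, crop, n)`), `n`, `negatives` (list of index vectors), `labels`.
#' @export
make_views <- function(batch, cfg = deformation_config(), n_negatives = NULL,
                       labels = NULL) {
  d <- dim(batch)
  if (length(d) != 4L) contract_error("batch must be a (C,H,W,n) array")
  n <- d[4]
  if (n < 1L) contract_error("batch is empty")
  out_size <- cfg$crop_size %||% d[2]
  if (out_size > d[2] || out_size > d[3])
    contract_error("crop_size ", out_size, " larger than image ", d[2], "x", d[3])
  views <- with_seed(cfg$seed, {
    vA <- array(0, c(d[1], out_size, out_size, n))
    vB <- array(0, c(d[1], out_size, out_size, n))
    for (s in seq_len(n)) {
      img <- array(batch[, , , s], d[1:3])
      vA[, , , s] <- deform_one(img, cfg, out_size)
      vB[, , , s] <- deform_one(img, cfg, out_size)
    }
    list(vA = vA, vB = vB)
  })
  negatives <- if (!is.null(n_negatives))
    lapply(seq_len(n), function(s) select_negatives(n, n_negatives, s))
  structure(list(view_A = views$vA, view_B = views$vB, n = n,
                 negatives = negatives, labels = labels),
            class = "view_batch")
}

#' Deform a test set once (robustness protocol)
#'
#' One deformed copy per image. With a [deformation_config()] the view
#' pipeline is applied once per image; with an [affine_config()] a random
#' rotation/shear/translation is applied with zero fill.
#'
#' @param batch Image batch `(C, H, W, n)`.
#' @param cfg A [deformation_config()] or [affine_config()].
#' @return Deformed batch with the same dimensions (deformation_config with a
#'   `crop_size` changes the spatial size accordingly).
#' @export
deform_test_set <- function(batch, cfg) {
  d <- dim(batch)
  if (length(d) != 4L) contract_error("batch must be a (C,H,W,n) array")
  if (inherits(cfg, "deformation_config")) {
    out_size <- cfg$crop_size %||% d[2]
    return(with_seed(cfg$seed, {
      out <- array(0, c(d[1], out_size, out_size, d[4]))
      for (s in seq_len(d[4]))
        out[, , , s] <- deform_one(array(batch[, , , s], d[1:3]), cfg, out_size)
      out
    }))
  }
  if (!inherits(cfg, "affine_config"))
    contract_error("cfg must be a deformation_config or affine_config")
  with_seed(cfg$seed, {
    out <- array(0, d)
    for (s in seq_len(d[4])) {
      th <- runif(1, -cfg$max_rotation, cfg$max_rotation) * pi / 180
      sh <- runif(1, -cfg$max_shear, cfg$max_shear) * pi / 180
      tx <- runif(1, -cfg$max_translate, cfg$max_translate) * d[3]
      ty <- runif(1, -cfg$max_translate, cfg$max_translate) * d[2]
      out[, , , s] <- affine_one(array(batch[, , , s], d[1:3]), th, sh, tx, ty)
    }
    out
  })
}

#' Apply a fixed affine transform to a batch
#'
#' Deterministic counterpart of the random affine deformation; useful for
#' oracle checks. Angles in radians, translation in pixels
#' (`tx` columns, `ty` rows), zero fill.
#'
#' @param batch Image batch `(C, H, W, n)`.
#' @param rotation,shear Radians.
#' @param tx,ty Translation in pixels.
#' @return Transformed batch.
#' @export
affine_batch <- function(batch, rotation = 0, shear = 0, tx = 0, ty = 0) {
  d <- dim(batch)
  if (length(d) != 4L) contract_error("batch must be a (C,H,W,n) array")
  out <- array(0, d)
  for (s in seq_len(d[4]))
    out[, , , s] <- affine_one(array(batch[, , , s], d[1:3]), rotation, shear, tx, ty)
  out
}

# rotation + shear about the image center followed by translation;
# implemented as inverse mapping with bilinear sampling and zero fill.
affine_one <- function(img, theta, shear, tx, ty) {
  d <- dim(img); H <- d[2]; W <- d[3]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  # forward map (col x, row y): dest = R %*% S %*% (src - c) + c + t
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  S <- matrix(c(1, 0, tan(shear), 1), 2, 2)
  A <- R %*% S
  Ainv <- solve(A)
  pos <- expand.grid(r = seq_len(H), cl = seq_len(W))
  dx <- pos$cl - cx - tx
  dy <- pos$r - cy - ty
  src_c <- Ainv[1, 1] * dx + Ainv[1, 2] * dy + cx
  src_r <- Ainv[2, 1] * dx + Ainv[2, 2] * dy + cy
  out <- bilinear_warp(img, src_r, src_c)
  dim(out) <- d
  out
}
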