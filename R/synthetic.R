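# Synthetic labeled image sets with known class structure and controllable
# nuisances. Classes are smooth geometric shape families whose identity
# survives the view deformations (crop, flip, jitter), so SSL positive pairs
# remain same-class and every training/evaluation path runs with no external
# data.

#' Available synthetic shape families
#' @return Character vector of family names.
#' @export
synthetic_families <- function() {
  c("blob", "ring", "cross", "diag", "hbar", "vbar", "checker", "dots")
}

#' Specification of a synthetic image dataset
#'
#' @param n_classes Number of classes (uses the first `n_classes` of
#'   `families`).
#' @param images_per_class Images per class (exact balance).
#' @param image_size Side length in pixels.
#' @param channels 1 (grayscale) or 3 (the gray shape tinted per draw).
#' @param families Shape family per class; defaults to
#'   [synthetic_families()].
#' @param position_jitter Center displacement range as a fraction of the
#'   image side (uniform per axis).
#' @param scale_range Shape scale factor interval.
#' @param intensity_range Peak intensity interval.
#' @param noise_sd Additive Gaussian pixel noise (clamped to \[0,1\]).
#' @param train_fraction Fraction of each class in the train split.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 4L, images_per_class = 500L,
                           image_size = 28L, channels = 1L,
                           families = synthetic_families(),
                           position_jitter = 0.2,
                           scale_range = c(0.6, 1.4),
                           intensity_range = c(0.4, 1),
                           noise_sd = 0.12,
                           train_fraction = 0.8,
                           seed = 1L) {
  if (n_classes > length(families))
    contract_error("n_classes exceeds available families")
  if (image_size < 8L) contract_error("image_size too small for the shape families")
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 families = families[seq_len(n_classes)],
                 position_jitter = position_jitter,
                 scale_range = scale_range,
                 intensity_range = intensity_range,
                 noise_sd = noise_sd,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# render one shape family on an H x H grid; soft (anti-aliased) edges
render_shape <- function(family, H, cr, cc, scale, intensity) {
  g <- expand.grid(r = seq_len(H), cl = seq_len(H))
  dr <- g$r - cr; dc <- g$cl - cc
  rad <- H / 4 * scale
  w <- H / 14 + 0.5
  v <- switch(family,
    blob = clamp01((rad - sqrt(dr^2 + dc^2)) / w + 0.5),
    ring = clamp01(1 - abs(sqrt(dr^2 + dc^2) - rad) / w),
    cross = pmax(clamp01(1 - abs(dr) / w) * (abs(dc) <= 1.4 * rad),
                 clamp01(1 - abs(dc) / w) * (abs(dr) <= 1.4 * rad)),
    diag = clamp01(1 - abs(dr - dc) / (w * 1.4)) * (sqrt(dr^2 + dc^2) <= 2.2 * rad),
    hbar = clamp01(1 - abs(dr) / w) * (abs(dc) <= 1.6 * rad),
    vbar = clamp01(1 - abs(dc) / w) * (abs(dr) <= 1.6 * rad),
    checker = 0.5 + 0.5 * sin(pi * dr / (rad / 1.2)) * sin(pi * dc / (rad / 1.2)),
    dots = {
      p <- pmax(rad, 3)
      mr <- ((dr + p / 2) %% p) - p / 2
      mc <- ((dc + p / 2) %% p) - p / 2
      clamp01((p / 3.2 - sqrt(mr^2 + mc^2)) / 1.2 + 0.5)
    },
    contract_error("unknown shape family ", family))
  matrix(v * intensity, H, H)
}

#' Generate a synthetic labeled dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset`: list with `train` and `test` (each
#'   `images` array `(C, H, W, n)` and integer `labels`), plus `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  H <- spec$image_size; C <- spec$channels
  ipc <- spec$images_per_class; K <- spec$n_classes
  N <- K * ipc
  with_seed(spec$seed, {
    images <- array(0, c(C, H, H, N))
    labels <- integer(N)
    i <- 0L
    for (k in seq_len(K)) {
      for (j in seq_len(ipc)) {
        i <- i + 1L
        labels[i] <- k
        jit <- spec$position_jitter * H
        cr <- (H + 1) / 2 + runif(1, -jit, jit)
        cc <- (H + 1) / 2 + runif(1, -jit, jit)
        sc <- runif(1, spec$scale_range[1], spec$scale_range[2])
        it <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
        img <- render_shape(spec$families[k], H, cr, cc, sc, it)
        if (spec$noise_sd > 0) img <- img + matrix(rnorm(H * H, 0, spec$noise_sd), H, H)
        img <- clamp01(img)
        if (C == 1L) {
          images[1, , , i] <- img
        } else {
          tint <- runif(C, 0.6, 1)
          for (ch in seq_len(C)) images[ch, , , i] <- img * tint[ch]
        }
      }
    }
    n_train <- round(spec$train_fraction * ipc)
    tr_idx <- unlist(lapply(seq_len(K), function(k)
      (k - 1L) * ipc + seq_len(n_train)))
    te_idx <- setdiff(seq_len(N), tr_idx)
    structure(list(
      train = list(images = images[, , , tr_idx, drop = FALSE],
                   labels = labels[tr_idx]),
      test = list(images = images[, , , te_idx, drop = FALSE],
                  labels = labels[te_idx]),
      spec = spec),
      class = "synthetic_dataset")
  })
}

#' Disjoint-class dataset pair (encoder set X, probe set Y)
#'
#' Realizes the transfer protocol of pretraining the encoder on one set of
#' classes and probing on a disjoint set: the first `n_classes` families form
#' the probe set, the next `n_classes` the pretraining set.
#'
#' @param spec A [synthetic_spec()]; `2 * n_classes` families must exist.
#' @return List with `pretrain` and `probe` `synthetic_dataset`s.
#' @export
generate_disjoint_pair <- function(spec = synthetic_spec()) {
  fams <- synthetic_families()
  K <- spec$n_classes
  if (2L * K > length(fams))
    contract_error("not enough families for a disjoint pair with ", K, " classes")
  probe_spec <- spec; probe_spec$families <- fams[seq_len(K)]
  pre_spec <- spec
  pre_spec$families <- fams[K + seq_len(K)]
  pre_spec$seed <- spec$seed + 1L
  list(pretrain = generate_synthetic(pre_spec),
       probe = generate_synthetic(probe_spec))
}

#' Export a synthetic dataset to disk
#'
#' Writes the arrays to `<path>/data.rds` and a JSON manifest (spec, seed,
#' split sizes) to `<path>/manifest.json`; round-trips losslessly via
#' [import_dataset()].
#'
#' @param ds A `synthetic_dataset`.
#' @param path Directory (created if missing).
#' @return `path`, invisibly.
#' @export
export_dataset <- function(ds, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ok <- tryCatch({
    saveRDS(ds[c("train", "test")], file.path(path, "data.rds"))
    TRUE
  }, error = function(e) contract_error("export to ", path, " failed: ", conditionMessage(e)))
  manifest <- c(unclass(ds$spec),
                list(n_train = length(ds$train$labels),
                     n_test = length(ds$test$labels)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a dataset written by [export_dataset()]
#' @param path Directory containing `data.rds` and `manifest.json`.
#' @return A `synthetic_dataset`.
#' @export
import_dataset <- function(path) {
  f <- file.path(path, "data.rds")
  if (!file.exists(f)) contract_error("no dataset found at ", path)
  blob <- readRDS(f)
  man <- jsonlite::read_json(file.path(path, "manifest.json"))
  spec <- synthetic_spec(n_classes = man$n_classes,
                         images_per_class = man$images_per_class,
                         image_size = man$image_size, channels = man$channels,
                         families = unlist(man$families),
                         position_jitter = man$position_jitter,
                         scale_range = unlist(man$scale_range),
                         intensity_range = unlist(man$intensity_range),
                         noise_sd = man$noise_sd,
                         train_fraction = man$train_fraction,
                         seed = man$seed)
  structure(list(train = blob$train, test = blob$test, spec = spec),
            class = "synthetic_dataset")
}
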