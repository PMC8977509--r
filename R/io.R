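# Image and config I/O: PNG import/export for visual inspection, array
# archives with JSON manifests for deformed fixture sets, and YAML network
# configs mirroring the printed architecture listings.

#' Read PNG files into an image batch
#'
#' @param files Character vector of PNG paths (equal dimensions).
#' @return Array `(C, H, W, n)` with values in \[0, 1\].
#' @export
read_png_images <- function(files) {
  if (!requireNamespace("png", quietly = TRUE))
    contract_error("the png package is required to read PNG files")
  imgs <- lapply(files, function(f) {
    x <- png::readPNG(f)
    if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
    if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]   # drop alpha
    aperm(x, c(3, 1, 2))                                  # H,W,C -> C,H,W
  })
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) {
    if (!all(dim(imgs[[i]]) == d))
      contract_error("image ", files[i], " has mismatched dimensions")
    out[, , , i] <- imgs[[i]]
  }
  out
}

#' Write an image batch as PNG files
#'
#' @param batch Array `(C, H, W, n)` in \[0, 1\].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The written file paths, invisibly.
#' @export
write_png_images <- function(batch, dir, prefix = "img") {
  if (!requireNamespace("png", quietly = TRUE))
    contract_error("the png package is required to write PNG files")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(batch)
  files <- file.path(dir, sprintf("%s_%04d.png", prefix, seq_len(d[4])))
  for (i in seq_len(d[4])) {
    img <- aperm(array(batch[, , , i], d[1:3]), c(2, 3, 1))  # -> H,W,C
    if (d[1] == 1L) img <- img[, , 1]
    png::writePNG(pmin(pmax(img, 0), 1), files[i])
  }
  invisible(files)
}

#' Export an image batch as an array archive with a JSON manifest
#'
#' Used for deformed fixture sets: the arrays go to `<path>/batch.rds`, the
#' manifest (applied parameters, any metadata passed) to
#' `<path>/manifest.json`.
#'
#' @param batch Array `(C, H, W, n)`.
#' @param path Directory.
#' @param manifest Named list recorded alongside (e.g. deformation
#'   parameters, seed).
#' @return `path`, invisibly.
#' @export
export_image_batch <- function(batch, path, manifest = list()) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  saveRDS(batch, file.path(path, "batch.rds"))
  jsonlite::write_json(c(list(dim = dim(batch)), manifest),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import an image batch written by [export_image_batch()]
#' @param path Directory.
#' @return List: `batch` (array), `manifest` (list).
#' @export
import_image_batch <- function(path) {
  f <- file.path(path, "batch.rds")
  if (!file.exists(f)) contract_error("no image batch found at ", path)
  list(batch = readRDS(f),
       manifest = jsonlite::read_json(file.path(path, "manifest.json")))
}

#' Write a network configuration as YAML
#' @param config A [network_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(config, path) {
  yaml::write_yaml(list(name = config$name,
                        input_shape = config$input_shape,
                        layers = lapply(config$layers, function(l)
                          Filter(Negate(is.null), unclass(l)))),
                   path)
  invisible(path)
}

#' Read a network configuration from YAML
#' @param path YAML file written by [write_network_config()] or by hand.
#' @return A [network_config()].
#' @export
read_network_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y$layers, function(l)
    layer_spec(l$kind, l$activation %||% "none",
               channels = l$channels,
               kernel = l$kernel %||% 3L, stride = l$stride %||% 1L,
               pool = l$pool %||% 2L))
  network_config(unlist(y$input_shape), specs, name = y$name %||% "yaml")
}
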