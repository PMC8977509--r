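#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package internals never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Checksums of all trainable parameter blocks
#'
#' Cheap numeric signatures (sum and sum of squares per block) used to assert
#' that parameter blocks were, or were not, modified by an operation.
#'
#' @param net A `plausnet_network`.
#' @return A tibble with columns `layer`, `block` ("W" or "B"), `sum`, `sumsq`.
#' @export
network_checksums <- function(net) {
  stopifnot(inherits(net, "plausnet_network"))
  rows <- list()
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    if (!is.null(ly$W)) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(layer = l, block = "W", sum = sum(ly$W), sumsq = sum(ly$W^2))
    }
    if (!is.null(ly$B)) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(layer = l, block = "B", sum = sum(ly$B), sumsq = sum(ly$B^2))
    }
  }
  do.call(rbind, rows)
}

# stop() with a consistent prefix for contract violations
contract_error <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
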