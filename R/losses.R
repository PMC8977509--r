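# Contrastive losses on embedding batches. Embedding matrices are (dim, n),
# one column per sample; the A branch holds anchors, the B branch positives,
# and negatives are columns of the B branch selected per anchor.

#' Configuration of the contrastive hinge loss
#'
#' The loss sums, over anchors, a positive hinge on the L1 distance between
#' the two views (active above margin `m1`) and negative hinges on the L1
#' distances to the selected negatives (active below margin `m2`). With
#' `block_gradient` (the default, the temporally most local variant) the
#' anchor-branch term is dropped from the top-layer update.
#'
#' @param m1 Positive-pair margin (>= 0).
#' @param m2 Negative-pair margin (> 0), typically > m1.
#' @param n_negatives Negatives per anchor (`T`).
#' @param block_gradient Drop the anchor-branch update term.
#' @return A `hinge_config`.
#' @export
hinge_config <- function(m1 = 1, m2 = 3, n_negatives = 5L, block_gradient = TRUE) {
  if (m1 < 0 || m2 <= 0) contract_error("need m1 >= 0 and m2 > 0")
  structure(list(m1 = m1, m2 = m2, n_negatives = as.integer(n_negatives),
                 block_gradient = isTRUE(block_gradient)),
            class = "hinge_config")
}

#' Margin preset for 28x28 grayscale data
#' @return A `hinge_config` with `m1 = 1`, `m2 = 1.5`.
#' @export
hinge_config_mnist <- function(n_negatives = 5L, block_gradient = TRUE)
  hinge_config(m1 = 1, m2 = 1.5, n_negatives = n_negatives,
               block_gradient = block_gradient)

check_emb <- function(emb_A, emb_B, negatives) {
  if (!is.matrix(emb_A) || !is.matrix(emb_B) || !all(dim(emb_A) == dim(emb_B)))
    contract_error("emb_A and emb_B must be matrices of identical shape")
  n <- ncol(emb_A)
  if (length(negatives) != n)
    contract_error("need one negative index set per anchor")
  for (s in seq_len(n)) {
    N <- negatives[[s]]
    if (any(N < 1 | N > n) || any(N == s))
      contract_error("invalid negative set for anchor ", s)
  }
  n
}

# L1 distances: positives per anchor, and per (anchor, negative) pair
pair_distances <- function(emb_A, emb_B, negatives) {
  n <- ncol(emb_A)
  d_pos <- colSums(abs(emb_A - emb_B))
  s_idx <- rep(seq_len(n), times = lengths(negatives))
  t_idx <- unlist(negatives, use.names = FALSE)
  d_neg <- if (length(t_idx))
    colSums(abs(emb_A[, s_idx, drop = FALSE] - emb_B[, t_idx, drop = FALSE]))
  else numeric(0)
  list(d_pos = d_pos, d_neg = d_neg, s_idx = s_idx, t_idx = t_idx)
}

#' Contrastive hinge loss
#'
#' `sum_s [ ||x_s^A - x_s^B||_1 - m1 ]_+ + sum_{t in N_s} [ m2 - ||x_s^A - x_t^B||_1 ]_+`
#' (a sum over the batch, not a mean).
#'
#' @param emb_A,emb_B Embedding matrices `(dim, n)`.
#' @param negatives List of per-anchor negative index sets (columns of
#'   `emb_B`), e.g. from [make_views()] or [select_negatives()].
#' @param cfg A [hinge_config()].
#' @return The loss scalar, with attribute `"breakdown"`: a tibble of
#'   per-term diagnostics (anchor, negative index or NA, distance, term).
#' @export
hinge_loss <- function(emb_A, emb_B, negatives, cfg = hinge_config()) {
  n <- check_emb(emb_A, emb_B, negatives)
  pd <- pair_distances(emb_A, emb_B, negatives)
  pos_terms <- pmax(pd$d_pos - cfg$m1, 0)
  neg_terms <- pmax(cfg$m2 - pd$d_neg, 0)
  breakdown <- tibble::tibble(
    anchor = c(seq_len(n), pd$s_idx),
    negative = c(rep(NA_integer_, n), pd$t_idx),
    distance = c(pd$d_pos, pd$d_neg),
    term = c(pos_terms, neg_terms))
  structure(sum(pos_terms) + sum(neg_terms), breakdown = breakdown)
}

# loss value only, no diagnostics: used in tight numeric loops
hinge_loss_value <- function(emb_A, emb_B, negatives, cfg) {
  pd <- pair_distances(emb_A, emb_B, negatives)
  sum(pmax(pd$d_pos - cfg$m1, 0)) + sum(pmax(cfg$m2 - pd$d_neg, 0))
}

#' Closed-form error signals of the contrastive hinge loss
#'
#' The top-layer error vectors: for anchor s,
#' `delta_A = 1{d_pos > m1} sgn(x^A - x^B) - sum_t 1{d_neg < m2} sgn(x^A - x_t^B)`,
#' `delta_B = -1{d_pos > m1} sgn(x^A - x^B)`, and per negative
#' `delta_neg = 1{d_neg < m2} sgn(x^A - x_t^B)`, with `sgn(0) = 0`. These are
#' the loss gradients with respect to the embeddings (off hinge boundaries).
#'
#' @inheritParams hinge_loss
#' @return An `error_signals` list: `delta_A`, `delta_B` (matrices `(dim, n)`),
#'   `delta_neg` (matrix `(dim, n_pairs)`), `s_idx`, `t_idx` (anchor/negative
#'   index per pair), and `blocked`.
#' @export
hinge_error_signals <- function(emb_A, emb_B, negatives, cfg = hinge_config()) {
  n <- check_emb(emb_A, emb_B, negatives)
  pd <- pair_distances(emb_A, emb_B, negatives)
  pos_active <- pd$d_pos > cfg$m1
  sgn_pos <- sign(emb_A - emb_B)
  delta_B <- -sweep(sgn_pos, 2, as.numeric(pos_active), `*`)
  delta_A0 <- -delta_B
  delta_neg <- NULL
  if (length(pd$t_idx)) {
    neg_active <- pd$d_neg < cfg$m2
    sgn_neg <- sign(emb_A[, pd$s_idx, drop = FALSE] - emb_B[, pd$t_idx, drop = FALSE])
    delta_neg <- sweep(sgn_neg, 2, as.numeric(neg_active), `*`)
    # anchor receives minus the sum of its active negative signs
    agg <- rowsum(t(delta_neg), group = pd$s_idx)
    full <- matrix(0, n, nrow(emb_A))
    full[as.integer(rownames(agg)), ] <- agg
    delta_A0 <- delta_A0 - t(full)
  } else {
    delta_neg <- matrix(0, nrow(emb_A), 0)
  }
  structure(list(delta_A = delta_A0, delta_B = delta_B, delta_neg = delta_neg,
                 s_idx = pd$s_idx, t_idx = pd$t_idx,
                 blocked = cfg$block_gradient),
            class = "error_signals")
}

#' Total embedding-space gradients per branch
#'
#' Collapses the per-pair error signals into the gradient of the loss with
#' respect to every A-branch and every B-branch embedding (a B sample
#' accumulates its positive term plus its terms as a negative of other
#' anchors). With `blocked`, the A-branch gradient is zeroed, mirroring the
#' short-term-memory reading of the anchor embedding.
#'
#' @param err An `error_signals` object.
#' @return List with matrices `grad_A`, `grad_B` of dim `(dim, n)`.
#' @export
branch_gradients <- function(err) {
  grad_A <- if (err$blocked) matrix(0, nrow(err$delta_A), ncol(err$delta_A))
            else err$delta_A
  grad_B <- err$delta_B
  if (length(err$t_idx)) {
    agg <- rowsum(t(err$delta_neg), group = err$t_idx)
    full <- matrix(0, ncol(grad_B), nrow(grad_B))
    full[as.integer(rownames(agg)), ] <- agg
    grad_B <- grad_B + t(full)
  }
  list(grad_A = grad_A, grad_B = grad_B)
}

#' Hebbian top-layer update of the contrastive hinge loss
#'
#' The descent increment of the top weight matrix:
#' `dW = -(delta_A x_A^T + delta_B x_B^T + sum_t delta_neg x_t^T)`, dropping
#' the anchor term under gradient blocking. `x_*` are the penultimate-layer
#' activations of each branch.
#'
#' @param err An `error_signals` object.
#' @param x_prev_A,x_prev_B Penultimate activations `(d_{L-1}, n)` of the two
#'   branches (negatives use columns of `x_prev_B`).
#' @return The unscaled weight increment (matrix like `W_L`); multiply by a
#'   learning rate before applying.
#' @export
top_layer_update <- function(err, x_prev_A, x_prev_B) {
  if (!all(dim(x_prev_A) == dim(x_prev_B)))
    contract_error("penultimate activations of the two branches differ in shape")
  if (ncol(x_prev_A) != ncol(err$delta_A))
    contract_error("batch size mismatch between error signals and activations")
  g <- branch_gradients(err)
  grad <- g$grad_A %*% t(x_prev_A) + g$grad_B %*% t(x_prev_B)
  -grad
}

#' Configuration of the SimCLR baseline loss
#' @param tau Temperature (> 0); 0.1 in the reference experiments.
#' @return A `simclr_config`.
#' @export
simclr_config <- function(tau = 0.1) {
  if (tau <= 0) contract_error("tau must be > 0")
  structure(list(tau = tau), class = "simclr_config")
}

#' SimCLR (normalized-temperature cross-entropy) loss
#'
#' Symmetric over the two branches; for each anchor the denominator ranges
#' over the other same-branch views (t != s) and all other-branch views.
#' Cosine similarities, temperature `tau`.
#'
#' @param emb_A,emb_B Embedding matrices `(dim, n)`, `n >= 2`.
#' @param cfg A [simclr_config()].
#' @return Loss scalar.
#' @export
simclr_loss <- function(emb_A, emb_B, cfg = simclr_config()) {
  if (!all(dim(emb_A) == dim(emb_B)))
    contract_error("emb_A and emb_B must have identical shape")
  n <- ncol(emb_A)
  if (n < 2) contract_error("SimCLR loss needs batch size >= 2")
  nA <- sqrt(colSums(emb_A^2)); nB <- sqrt(colSums(emb_B^2))
  if (any(nA == 0) || any(nB == 0))
    stop("zero-norm embedding: cosine similarity undefined", call. = FALSE)
  An <- sweep(emb_A, 2, nA, `/`); Bn <- sweep(emb_B, 2, nB, `/`)
  SAA <- crossprod(An, An) / cfg$tau
  SBB <- crossprod(Bn, Bn) / cfg$tau
  SAB <- crossprod(An, Bn) / cfg$tau   # [s,t] = sim(A_s, B_t)
  loss <- 0
  for (s in seq_len(n)) {
    denA <- sum(exp(SAA[s, -s])) + sum(exp(SAB[s, ]))
    loss <- loss - (SAB[s, s] - log(denA))
    denB <- sum(exp(SBB[s, -s])) + sum(exp(SAB[, s]))
    loss <- loss - (SAB[s, s] - log(denB))
  }
  loss
}
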