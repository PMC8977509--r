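# Linear-probe evaluation of frozen embeddings, the deformation-robustness
# protocol and margin diagnostics.

#' Train a multinomial linear classifier on fixed features
#'
#' A single linear layer (with bias) trained on softmax cross-entropy with
#' the configured optimizer; the probe used by linear evaluation and the
#' classifier head shared by the supervised comparisons.
#'
#' @param features Matrix `(d, n)` (columns are samples).
#' @param labels Integer labels `1..K`.
#' @param epochs Passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Learning rate (0.001 in the reference protocol).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Integer seed.
#' @return List: `W` (K x d), `b` (K), `history` (tibble: epoch, loss, accuracy).
#' @export
train_linear_classifier <- function(features, labels, epochs = 100L,
                                    batch_size = 64L, lr = 1e-3,
                                    optimizer = "adam", seed = 1L) {
  if (ncol(features) != length(labels))
    contract_error("feature columns (", ncol(features), ") != labels (", length(labels), ")")
  d <- nrow(features); n <- ncol(features); K <- max(labels)
  W <- matrix(0, K, d); b <- numeric(K)
  mW <- vW <- W * 0; mb <- vb <- b * 0; t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  ords <- derive_seeds(seed, epochs)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(ords[ep], sample.int(n))
    losses <- c(); accs <- c()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      X <- features[, idx, drop = FALSE]
      y <- labels[idx]; m <- length(idx)
      Z <- W %*% X + b
      P <- softmax_cols(Z)
      Y <- matrix(0, K, m); Y[cbind(y, seq_len(m))] <- 1
      losses <- c(losses, -sum(log(pmax(P[Y == 1], 1e-12))) / m)
      accs <- c(accs, mean(max.col(t(Z)) == y))
      dZ <- (P - Y) / m
      gW <- tcrossprod(dZ, X); gb <- rowSums(dZ)
      if (optimizer == "sgd") {
        W <- W - lr * gW; b <- b - lr * gb
      } else {
        t <- t + 1L
        mW <- beta1 * mW + (1 - beta1) * gW; vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        W <- W - lr * (mW / (1 - beta1^t)) / (sqrt(vW / (1 - beta2^t)) + eps)
        b <- b - lr * (mb / (1 - beta1^t)) / (sqrt(vb / (1 - beta2^t)) + eps)
      }
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses), accuracy = mean(accs))
  }
  list(W = W, b = b, history = do.call(rbind, hist))
}

classifier_accuracy <- function(clf, features, labels) {
  Z <- clf$W %*% features + clf$b
  mean(max.col(t(Z)) == labels)
}

#' Linear evaluation of a frozen encoder
#'
#' Removes the projection head, extracts the flattened last-conv-block
#' features of the train and test sets, trains a linear classifier on the
#' train features and reports held-out accuracy. The encoder receives no
#' updates (asserted by parameter checksums).
#'
#' @param net A `plausnet_network` (trained or random).
#' @param train,test Lists with `images` (`(C,H,W,n)` array) and `labels`.
#' @param epochs,lr,optimizer,seed Probe settings, see
#'   [train_linear_classifier()].
#' @return An `eval_report` (list with `probe_accuracy`, `train_accuracy`,
#'   `classifier`, `seed`, `encoder_config`).
#' @export
linear_evaluation <- function(net, train, test, epochs = 100L, lr = 1e-3,
                              optimizer = "adam", seed = 1L) {
  before <- network_checksums(net)
  ftr <- embed(net, train$images, strip_head = TRUE)
  fte <- embed(net, test$images, strip_head = TRUE)
  clf <- train_linear_classifier(ftr, train$labels, epochs = epochs, lr = lr,
                                 optimizer = optimizer, seed = seed)
  stopifnot(identical(before, network_checksums(net)))
  structure(list(probe_accuracy = classifier_accuracy(clf, fte, test$labels),
                 train_accuracy = classifier_accuracy(clf, ftr, train$labels),
                 robustness_accuracy = NA_real_,
                 classifier = clf, seed = seed,
                 encoder_config = net$config$name),
            class = "eval_report")
}

#' Deformation-robustness evaluation
#'
#' Probe trained on undeformed features, tested on a deformed copy of the
#' test set; optionally paired with a supervised baseline (same encoder
#' architecture, trained end-to-end on the labeled train set with the same
#' classifier hyperparameters for its head phase).
#'
#' @param net Frozen encoder.
#' @param train,test Labeled sets as in [linear_evaluation()].
#' @param deform Deformation applied to the test images: a
#'   [deformation_config()] or [affine_config()].
#' @param supervised_net Optional supervised comparison network trained with
#'   [train_supervised()]; its accuracy on the deformed test set is reported.
#' @param epochs,lr,optimizer,seed As in [linear_evaluation()].
#' @return An `eval_report` with `probe_accuracy` (undeformed test),
#'   `robustness_accuracy` (deformed test), and if a supervised net is given,
#'   `supervised_accuracy` / `supervised_robustness`.
#' @export
robustness_evaluation <- function(net, train, test, deform = affine_config(),
                                  supervised_net = NULL, epochs = 100L,
                                  lr = 1e-3, optimizer = "adam", seed = 1L) {
  deformed <- deform_test_set(test$images, deform)
  rep0 <- linear_evaluation(net, train, test, epochs = epochs, lr = lr,
                            optimizer = optimizer, seed = seed)
  fdef <- embed(net, deformed, strip_head = TRUE)
  rep0$robustness_accuracy <- classifier_accuracy(rep0$classifier, fdef, test$labels)
  if (!is.null(supervised_net)) {
    acc <- function(nn, imgs) {
      Z <- embed(nn, imgs, strip_head = FALSE)
      mean(max.col(t(Z)) == test$labels)
    }
    rep0$supervised_accuracy <- acc(supervised_net, test$images)
    rep0$supervised_robustness <- acc(supervised_net, deformed)
  }
  rep0
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> encoder:", x$encoder_config, "\n")
  cat(sprintf("  probe accuracy       %.4f\n", x$probe_accuracy))
  if (!is.na(x$robustness_accuracy))
    cat(sprintf("  robustness accuracy  %.4f\n", x$robustness_accuracy))
  if (!is.null(x$supervised_robustness))
    cat(sprintf("  supervised (deformed) %.4f\n", x$supervised_robustness))
  invisible(x)
}

#' Tidy an evaluation report
#' @method tidy eval_report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble of the report's accuracies and metadata.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(probe_accuracy = x$probe_accuracy,
                 train_accuracy = x$train_accuracy,
                 robustness_accuracy = x$robustness_accuracy,
                 supervised_accuracy = x$supervised_accuracy %||% NA_real_,
                 supervised_robustness = x$supervised_robustness %||% NA_real_,
                 encoder = x$encoder_config, seed = x$seed)
}

#' Positive/negative distance histograms and margin suggestion
#'
#' The L1 distances between positive pairs and between anchors and their
#' selected negatives, with suggested margins from configurable quantiles —
#' the diagnostic used to pick `m1`/`m2` on new data.
#'
#' @param emb_A,emb_B Embedding matrices `(dim, n)`.
#' @param negatives Per-anchor negative index lists.
#' @param pos_quantile Quantile of the positive distances suggested as `m1`.
#' @param neg_quantile Quantile of the negative distances suggested as `m2`.
#' @return A `margin_histogram`: tibble of distances (`pair`, `distance`)
#'   with attributes `m1`, `m2`.
#' @export
margin_histogram <- function(emb_A, emb_B, negatives,
                             pos_quantile = 0.5, neg_quantile = 0.25) {
  n <- check_emb(emb_A, emb_B, negatives)
  pd <- pair_distances(emb_A, emb_B, negatives)
  out <- tibble::tibble(
    pair = c(rep("positive", n), rep("negative", length(pd$d_neg))),
    distance = c(pd$d_pos, pd$d_neg))
  attr(out, "m1") <- unname(stats::quantile(pd$d_pos, pos_quantile))
  attr(out, "m2") <- if (length(pd$d_neg))
    unname(stats::quantile(pd$d_neg, neg_quantile)) else NA_real_
  class(out) <- c("margin_histogram", class(out))
  out
}

#' Histogram plot of positive/negative embedding distances
#' @method autoplot margin_histogram
#' @param object A `margin_histogram`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.margin_histogram <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, fill = .data$pair)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = attr(object, "m1"), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "m2")) +
    ggplot2::labs(x = "L1 distance", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy
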