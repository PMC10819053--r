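#' Huber loss
#'
#' Robust regression loss used for the signal-reconstruction task:
#' quadratic (`r^2/2`) for residuals with `|r| <= delta`, linear
#' (`delta * (|r| - delta/2)`) beyond; continuous and once-differentiable at
#' the junction. The batch value is the mean over all elements.
#'
#' @param residual numeric vector/array of residuals (prediction - target).
#' @param delta transition point between the quadratic and linear regimes.
#' @return mean Huber loss (scalar).
#' @export
huber_loss <- function(residual, delta = 1) {
  stopifnot(delta > 0)
  a <- abs(residual)
  mean(ifelse(a <= delta, 0.5 * residual^2, delta * (a - 0.5 * delta)))
}

huber_grad <- function(residual, delta = 1) pmin(pmax(residual, -delta), delta)

#' Cross-entropy loss
#'
#' Mean negative log-probability of the true class. Probabilities are
#' clipped to `[1e-7, 1]` before the logarithm, so a zero probability on the
#' true class contributes `-log(1e-7)` rather than infinity.
#'
#' @param y_true integer class labels (0-based, length N) or an N x K
#'   one-hot matrix.
#' @param probs N x K matrix of class probabilities (rows on the simplex).
#' @return mean cross-entropy (scalar).
#' @export
cross_entropy_loss <- function(y_true, probs) {
  if (is.matrix(y_true)) {
    if (!all(dim(y_true) == dim(probs)))
      stop("one-hot labels and probabilities must have identical dimensions")
    idx <- max.col(y_true, ties.method = "first")
  } else {
    if (length(y_true) != nrow(probs))
      stop("length of labels must equal the number of probability rows")
    idx <- as.integer(y_true) + 1L
    if (any(idx < 1L | idx > ncol(probs)))
      stop("labels out of range for the probability matrix")
  }
  p <- probs[cbind(seq_len(nrow(probs)), idx)]
  mean(-log(pmin(pmax(p, 1e-7), 1)))
}

one_hot <- function(labels, K) {
  y <- matrix(0, length(labels), K)
  y[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  y
}

#' Composite multi-task loss
#'
#' Weighted sum `w_rec * Huber(reconstruction) + w_cls * cross-entropy`,
#' with the components reported separately. Variants without a head must
#' have the corresponding weight at zero.
#'
#' @param outputs a list as returned by [model_forward()] (elements
#'   `reconstruction` and/or `class_probs`).
#' @param batch the standardized [window_batch()] the outputs were computed
#'   from (targets for both tasks).
#' @param control a [train_config()] providing `loss_weights` and
#'   `huber_delta`.
#' @return list with `total`, `reconstruction`, `classification`.
#' @export
composite_loss <- function(outputs, batch, control = train_config()) {
  w <- control$loss_weights
  rec <- 0; cls <- 0
  if (w[1] > 0) {
    if (is.null(outputs$reconstruction))
      stop("reconstruction weight > 0 but the model has no decoder head")
    rec <- huber_loss(outputs$reconstruction - batch$windows, control$huber_delta)
  }
  if (w[2] > 0) {
    if (is.null(outputs$class_probs))
      stop("classification weight > 0 but the model has no classifier head")
    cls <- cross_entropy_loss(batch$labels, outputs$class_probs)
  }
  list(total = w[1] * rec + w[2] * cls, reconstruction = rec, classification = cls)
}
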