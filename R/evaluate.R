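#' Confusion matrix
#'
#' @param y_true,y_pred integer class labels in `[0, K)`.
#' @param K number of classes.
#' @return K x K integer matrix; entry (i, j) counts samples of true class
#'   `i - 1` predicted as class `j - 1` (rows = true, columns = predicted).
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have the same length")
  if (any(y_true < 0L | y_true >= K) || any(y_pred < 0L | y_pred >= K))
    stop(sprintf("labels must lie in [0, %d)", K))
  cm <- matrix(0L, K, K,
               dimnames = list(true = 0:(K - 1L), predicted = 0:(K - 1L)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Per-class classification report
#'
#' Per-class precision (`TP / (TP + FP)`), recall (`TP / (TP + FN)`) and F1
#' (harmonic mean), each reported as 0 when its denominator is 0, plus
#' accuracy, macro (unweighted) averages over all K classes, and weighted
#' (support-proportional) averages over the classes present in `y_true`.
#'
#' @param y_true,y_pred integer class labels in `[0, K)`.
#' @param K number of classes.
#' @param class_names optional character vector of length K.
#' @return an object of class `eval_report`: list with `per_class` (data
#'   frame), `accuracy`, `macro_avg`, `weighted_avg`, `confusion` and `n`.
#' @export
classification_report <- function(y_true, y_pred, K, class_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, K)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  if (is.null(class_names)) class_names <- as.character(0:(K - 1L))
  per_class <- data.frame(class = class_names, precision = precision,
                          recall = recall, f1 = f1, support = as.integer(support),
                          row.names = NULL)
  n <- length(y_true)
  wt <- support / n
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / n,
    macro_avg = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted_avg = c(precision = sum(wt * precision), recall = sum(wt * recall),
                     f1 = sum(wt * f1)),
    confusion = cm, n = n), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("\naccuracy: %.*f  (n = %d)\n", digits, x$accuracy, x$n))
  cat(sprintf("macro avg:    P %.*f  R %.*f  F1 %.*f\n", digits,
              x$macro_avg["precision"], digits, x$macro_avg["recall"],
              digits, x$macro_avg["f1"]))
  cat(sprintf("weighted avg: P %.*f  R %.*f  F1 %.*f\n", digits,
              x$weighted_avg["precision"], digits, x$weighted_avg["recall"],
              digits, x$weighted_avg["f1"]))
  invisible(x)
}

#' Reconstruction root-mean-square error
#'
#' @param x,x_hat arrays of identical shape (N x C x T), typically the
#'   standardized input and its reconstruction.
#' @return list with `overall` (RMSE over all elements) and `per_channel`
#'   (length-C vector, RMSE over N x T elements per channel).
#' @export
reconstruction_rmse <- function(x, x_hat) {
  if (!all(dim(x) == dim(x_hat)))
    stop("`x` and `x_hat` must have identical dimensions")
  se <- (x - x_hat)^2
  per_channel <- if (length(dim(x)) == 3L)
    sqrt(apply(se, 2L, mean)) else sqrt(mean(se))
  list(overall = sqrt(mean(se)), per_channel = per_channel)
}

#' Extract the flattened latent embedding of a batch
#'
#' The features are exactly the classifier head's input: the shared latent
#' tensor flattened to `N x (T/16 * latent_channels)`, computed in inference
#' mode (deterministic for fixed weights).
#'
#' @param model an `mcae_net` or fitted [mcae()] object.
#' @param batch a standardized [window_batch()].
#' @return an object of class `latent_embedding`: list with `features`
#'   (N x D matrix), `labels` and `subject_ids`.
#' @export
extract_latent <- function(model, batch) {
  out <- model_forward(model, batch)
  lat <- out$latent
  d <- dim(lat)
  dim(lat) <- c(d[1], d[2] * d[3])
  structure(list(features = lat, labels = batch$labels,
                 subject_ids = batch$subject_ids),
            class = "latent_embedding")
}

#' Project an embedding onto its principal components
#'
#' Centers the features (no rescaling) and projects onto the top-variance
#' orthonormal directions. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making the projection
#' deterministic. If the feature rank is below `n_components` the missing
#' components are zero-padded with a warning.
#'
#' @param embedding a `latent_embedding` from [extract_latent()], or a
#'   numeric matrix of features.
#' @param n_components number of components to keep.
#' @return list with `projection` (N x n_components), `explained_variance_ratio`
#'   (fractions of total feature variance, non-increasing), `loadings` and
#'   `labels` (when available).
#' @export
pca_project <- function(embedding, n_components = 3L) {
  feats <- if (inherits(embedding, "latent_embedding")) embedding$features
           else as.matrix(embedding)
  N <- nrow(feats)
  if (N <= n_components)
    stop(sprintf("need more than %d observations for %d components",
                 n_components, n_components))
  pc <- stats::prcomp(feats, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  k_avail <- sum(pc$sdev > 1e-12)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  proj <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                 # sign convention
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) { rot[, j] <- -rot[, j]; proj[, j] <- -proj[, j] }
  }
  evr <- (pc$sdev[seq_len(k)]^2) / total_var
  if (k < n_components || k_avail < n_components) {
    if (ncol(proj) < n_components) {
      warning(sprintf("feature rank %d < %d components; padding with zeros",
                      k, n_components))
      pad <- n_components - ncol(proj)
      proj <- cbind(proj, matrix(0, N, pad))
      rot <- cbind(rot, matrix(0, nrow(rot), pad))
      evr <- c(evr, rep(0, pad))
    }
  }
  colnames(proj) <- paste0("pc", seq_len(n_components))
  list(projection = proj, explained_variance_ratio = evr, loadings = rot,
       labels = if (inherits(embedding, "latent_embedding")) embedding$labels else NULL)
}

#' Activation-function reconstruction comparison
#'
#' Trains the unsupervised auto-encoder once per (activation, seed) pair on
#' the same splits and records the final validation Huber loss together with
#' the reconstruction RMSE on the test split, overall and per class. Also
#' reports, for each activation, the best- and worst-reconstructed test
#' window per class (by per-window RMSE).
#'
#' @param splits list with standardized `train`, `val`, `test`
#'   [window_batch()] elements (as returned by [generate_dataset()]).
#' @param activations character vector of activation names.
#' @param seeds integer vector of training seeds.
#' @param config optional [model_config()] template (variant forced to AE;
#'   activation overridden per run).
#' @param control a [train_config()]; `loss_weights` forced to `(1, 0)`.
#' @param verbose print progress.
#' @return an object of class `activation_comparison`: list with `table`
#'   (one row per activation x seed), `summary` (median over seeds per
#'   activation, ranked), `per_class` (long data frame of per-class RMSE)
#'   and `examples`.
#' @export
activation_comparison <- function(splits, activations = c("relu", "selu", "elu", "swish"),
                                  seeds = 1:3, config = NULL,
                                  control = train_config(max_epochs = 15L),
                                  verbose = FALSE) {
  stopifnot(length(activations) >= 1L, length(seeds) >= 1L)
  d <- dim(splits$train$windows)
  classes <- sort(unique(c(splits$train$labels, splits$test$labels)))
  rows <- list(); pcls <- list(); examples <- list()
  for (act in activations) {
    for (sd in seeds) {
      cfg <- if (is.null(config))
        model_config(n_channels = d[2], window_length = d[3], variant = "AE",
                     activation = act)
      else {
        cfg2 <- config; cfg2$variant <- "AE"; cfg2$activation <- act
        cfg2$n_classes <- NULL
        cfg2
      }
      ctl <- control
      ctl$loss_weights <- c(1, 0)
      ctl$seed <- as.integer(sd)
      if (verbose) message(sprintf("activation %s, seed %d", act, sd))
      fit <- mcae(splits$train, splits$val, cfg, ctl)
      xh <- predict(fit, splits$test, type = "reconstruction")
      x <- splits$test$windows
      rmse <- reconstruction_rmse(x, xh)
      win_rmse <- sqrt(apply((x - xh)^2, 1L, mean))
      rows[[length(rows) + 1L]] <- data.frame(
        activation = act, seed = sd,
        val_huber = fit$history$best_val_loss,
        rmse_overall = rmse$overall)
      for (cl in classes) {
        sel <- which(splits$test$labels == cl)
        pcls[[length(pcls) + 1L]] <- data.frame(
          activation = act, seed = sd, class = cl,
          rmse = sqrt(mean((x[sel, , , drop = FALSE] - xh[sel, , , drop = FALSE])^2)))
        examples[[length(examples) + 1L]] <- data.frame(
          activation = act, seed = sd, class = cl,
          best_window = sel[which.min(win_rmse[sel])],
          worst_window = sel[which.max(win_rmse[sel])],
          best_rmse = min(win_rmse[sel]), worst_rmse = max(win_rmse[sel]))
      }
    }
  }
  table <- do.call(rbind, rows)
  per_class <- do.call(rbind, pcls)
  agg <- stats::aggregate(cbind(val_huber, rmse_overall) ~ activation, table, stats::median)
  agg <- agg[order(agg$rmse_overall), ]
  structure(list(table = table, summary = agg, per_class = per_class,
                 examples = do.call(rbind, examples)),
            class = "activation_comparison")
}

#' @export
print.activation_comparison <- function(x, ...) {
  cat("Reconstruction comparison (median over seeds, ranked by RMSE):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
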