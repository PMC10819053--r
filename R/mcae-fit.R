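#' Fit a multi-channel auto-encoder network
#'
#' The package's main fitting function: assembles the requested network
#' variant, trains it on standardized window batches with Adam and early
#' stopping, and returns a fitted-model object with the usual accessor
#' methods ([predict.mcae()], [summary.mcae()], [plot.mcae()],
#' [residuals.mcae()], [coef.mcae()]).
#'
#' Both batches must already be standardized with statistics fitted on the
#' training split only (see [fit_standardizer()] / [standardize()];
#' [generate_dataset()] returns splits in this form).
#'
#' @param train standardized training [window_batch()].
#' @param val standardized validation [window_batch()] monitored for early
#'   stopping.
#' @param config a [model_config()]; defaults to an MCAE sized from `train`.
#' @param control a [train_config()].
#' @param verbose print one line per epoch.
#' @return an object of class `mcae`: a list with `net` (the trained
#'   `mcae_net`), `history` (a `train_history`), `config` and `control`.
#' @examples
#' \donttest{
#' splits <- generate_dataset(default_benchmark_spec(), n_subjects = 4, seed = 1)
#' cfg <- model_config(n_channels = 6, window_length = 128, n_classes = 4)
#' fit <- mcae(splits$train, splits$val, cfg,
#'             train_config(max_epochs = 3, seed = 1))
#' pred <- predict(fit, splits$test)
#' }
#' @export
mcae <- function(train, val, config = NULL, control = train_config(),
                 verbose = FALSE) {
  stopifnot(inherits(train, "window_batch"), inherits(val, "window_batch"))
  if (is.null(config)) {
    d <- dim(train$windows)
    config <- model_config(n_channels = d[2], window_length = d[3],
                          n_classes = length(unique(train$labels)))
  }
  set.seed(control$seed)
  net <- assemble(config)
  res <- train_network(net, train, val, control, verbose = verbose)
  structure(list(net = res$net, history = res$history, config = config,
                 control = control, channel_names = train$channel_names),
            class = "mcae")
}

#' @export
print.mcae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Multi-channel auto-encoder fit (variant %s)\n", cfg$variant))
  cat(sprintf("  channels: %d   window: %d samples   latent: %d x %d   activation: %s\n",
              cfg$n_channels, cfg$window_length, cfg$window_length %/% 16L,
              cfg$latent_channels, cfg$activation))
  if (!is.null(cfg$n_classes)) cat(sprintf("  classes: %d\n", cfg$n_classes))
  cat(sprintf("  trainable parameters: %d\n", count_trainable_parameters(x$net)))
  h <- x$history
  cat(sprintf("  trained %d epoch(s); best epoch %d, validation loss %.5f\n",
              h$stop_epoch, h$best_epoch, h$best_val_loss))
  invisible(x)
}

#' Summarize a fitted network
#'
#' @param object a fitted [mcae()] object.
#' @param ... unused.
#' @return a `summary.mcae` list with the layer table, parameter total and
#'   final training metrics.
#' @export
summary.mcae <- function(object, ...) {
  h <- object$history
  ep <- h$epochs
  last <- ep[nrow(ep), ]
  structure(list(config = object$config,
                 description = object$net$description,
                 n_params = count_trainable_parameters(object$net),
                 stop_epoch = h$stop_epoch, best_epoch = h$best_epoch,
                 best_val_loss = h$best_val_loss,
                 final = last),
            class = "summary.mcae")
}

#' @export
print.summary.mcae <- function(x, ...) {
  cat(sprintf("Variant %s  (%d trainable parameters)\n", x$config$variant, x$n_params))
  print(x$description, row.names = FALSE)
  cat(sprintf("total trainable: %d\n", x$n_params))
  cat(sprintf("epochs run: %d   best epoch: %d   best val loss: %.6f\n",
              x$stop_epoch, x$best_epoch, x$best_val_loss))
  if (!is.na(x$final$val_accuracy))
    cat(sprintf("final val accuracy: %.4f\n", x$final$val_accuracy))
  invisible(x)
}

#' Predictions from a fitted network
#'
#' @param object a fitted [mcae()] object.
#' @param newdata a standardized [window_batch()].
#' @param type `"class"` (0-based predicted labels), `"prob"` (N x K class
#'   probabilities), `"reconstruction"` (N x C x T array) or `"latent"`
#'   (N x T/16 x latent_channels array).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.mcae <- function(object, newdata,
                         type = c("class", "prob", "reconstruction", "latent"),
                         ...) {
  type <- match.arg(type)
  out <- model_forward(object$net, newdata)
  switch(type,
    class = {
      if (is.null(out$class_probs))
        stop("variant ", object$config$variant, " has no classifier head")
      max.col(out$class_probs, ties.method = "first") - 1L
    },
    prob = {
      if (is.null(out$class_probs))
        stop("variant ", object$config$variant, " has no classifier head")
      out$class_probs
    },
    reconstruction = {
      if (is.null(out$reconstruction))
        stop("variant ", object$config$variant, " has no decoder")
      out$reconstruction
    },
    latent = out$latent)
}

#' Reconstruction residuals of a fitted network
#'
#' @param object a fitted [mcae()] object with a decoder.
#' @param newdata a standardized [window_batch()].
#' @param ... unused.
#' @return array N x C x T of `reconstruction - input`.
#' @export
residuals.mcae <- function(object, newdata, ...) {
  predict(object, newdata, type = "reconstruction") - newdata$windows
}

#' Trainable parameters of a fitted network
#'
#' @param object a fitted [mcae()] object.
#' @param flatten return one numeric vector instead of the nested list.
#' @param ... unused.
#' @return nested list of parameter arrays, or a numeric vector.
#' @export
coef.mcae <- function(object, flatten = FALSE, ...) {
  if (flatten) flatten_tree(object$net$params) else object$net$params
}

#' Plot training history
#'
#' Training and validation total loss per epoch, with the best (restored)
#' epoch marked.
#'
#' @param x a fitted [mcae()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mcae <- function(x, ...) {
  ep <- x$history$epochs
  graphics::matplot(ep$epoch, cbind(ep$train_total, ep$val_total), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "total loss", ...)
  graphics::abline(v = x$history$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
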