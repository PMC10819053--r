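#' Training configuration
#'
#' Optimization settings for [train_network()]: Adam with learning rate
#' 0.001 (and the conventional beta/epsilon defaults), mini-batches of 128,
#' equal task weights, and early stopping on the validation total loss with
#' a minimum improvement of 0.0001 and a patience of 10 epochs, restoring
#' the best weights.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param loss_weights length-2 numeric `(w_rec, w_cls)`; both non-negative,
#'   not both zero.
#' @param huber_delta Huber transition point for the reconstruction loss.
#' @param min_delta minimum decrease of the monitored validation loss for an
#'   epoch to count as an improvement.
#' @param patience consecutive non-improving epochs tolerated before
#'   stopping.
#' @param restore_best restore the parameters of the best epoch after
#'   stopping.
#' @param seed integer seed driving weight initialization and mini-batch
#'   shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128L,
                         max_epochs = 50L, loss_weights = c(1, 1),
                         huber_delta = 1, min_delta = 1e-4, patience = 10L,
                         restore_best = TRUE, seed = 1L) {
  if (length(loss_weights) != 2L || any(loss_weights < 0) || sum(loss_weights) == 0)
    stop("`loss_weights` must be two non-negative numbers, not both zero")
  if (min_delta < 0) stop("`min_delta` must be >= 0")
  if (patience < 1L) stop("`patience` must be >= 1")
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 loss_weights = as.numeric(loss_weights),
                 huber_delta = huber_delta, min_delta = min_delta,
                 patience = as.integer(patience),
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping decision on a validation-loss sequence
#'
#' An epoch improves iff its loss is below the best loss so far minus
#' `min_delta`; training stops once `patience` consecutive non-improving
#' epochs have elapsed. The first epoch always counts as improving.
#'
#' @param val_losses numeric vector of per-epoch validation losses (in
#'   order).
#' @param min_delta minimum decrease that counts as an improvement.
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with `stop` (logical) and `best_epoch` (1-based index of
#'   the last improving epoch).
#' @export
early_stop_check <- function(val_losses, min_delta = 1e-4, patience = 10L) {
  stopifnot(length(val_losses) >= 1L)
  best <- val_losses[1]
  best_epoch <- 1L
  wait <- 0L
  for (i in seq_along(val_losses)) {
    if (i == 1L) next
    if (val_losses[i] < best - min_delta) {
      best <- val_losses[i]
      best_epoch <- i
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(stop = TRUE, best_epoch = best_epoch))
    }
  }
  list(stop = FALSE, best_epoch = best_epoch)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(opt, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# Losses (and accuracy) of a batch in inference mode, computed in chunks to
# bound memory.
eval_batch_loss <- function(net, batch, control, chunk = 512L) {
  N <- n_windows(batch)
  g <- cfg_geometry(net$config)
  w <- control$loss_weights
  rec_sum <- 0; cls_sum <- 0; correct <- 0L
  has_rec <- g$has_dec && w[1] > 0
  has_cls <- g$has_cls
  for (lo in seq.int(1L, N, by = chunk)) {
    hi <- min(lo + chunk - 1L, N)
    sub <- batch_subset(batch, lo:hi)
    x <- aperm(sub$windows, c(1, 3, 2))
    fw <- net_forward(net, x, training = FALSE)
    n <- hi - lo + 1L
    if (has_rec) {
      r <- fw$out$reconstruction - x
      rec_sum <- rec_sum + huber_loss(r, control$huber_delta) * n
    }
    if (has_cls) {
      cls_sum <- cls_sum + cross_entropy_loss(sub$labels, fw$out$class_probs) * n
      pred <- max.col(fw$out$class_probs, ties.method = "first") - 1L
      correct <- correct + sum(pred == sub$labels)
    }
  }
  rec <- rec_sum / N; cls <- cls_sum / N
  list(total = w[1] * rec + w[2] * cls, reconstruction = rec,
       classification = cls,
       accuracy = if (has_cls) correct / N else NA_real_)
}

#' Train a network with Adam and early stopping
#'
#' Mini-batch training of any assembled variant: shuffled (seeded)
#' mini-batches, Adam updates on the composite Huber + cross-entropy loss,
#' per-epoch validation in inference mode, early stopping on the validation
#' total loss, and restoration of the best epoch's parameters (including
#' batch-norm running moments). Batches are expected to be standardized
#' with statistics fitted on the training split only.
#'
#' @param net an `mcae_net` from [assemble()].
#' @param train,val standardized [window_batch()] training and validation
#'   splits.
#' @param control a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `net` (trained network) and `history` (class
#'   `train_history`: per-epoch data frame plus `stop_epoch`, `best_epoch`,
#'   `best_val_loss`).
#' @export
train_network <- function(net, train, val, control = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(net, "mcae_net"), inherits(control, "train_config"))
  if (is.null(train) || n_windows(train) == 0L) stop("empty training split")
  if (is.null(val) || n_windows(val) == 0L) stop("empty validation split")
  cfg <- net$config
  g <- cfg_geometry(cfg)
  w <- control$loss_weights
  if (w[1] > 0 && !g$has_dec)
    stop("reconstruction weight > 0 but variant ", cfg$variant, " has no decoder")
  if (w[2] > 0 && !g$has_cls)
    stop("classification weight > 0 but variant ", cfg$variant, " has no classifier")
  if (g$has_cls && any(train$labels >= cfg$n_classes))
    stop("training labels exceed n_classes - 1")

  set.seed(control$seed)
  N <- n_windows(train)
  x_all <- aperm(train$windows, c(1, 3, 2))
  y_all <- if (g$has_cls) one_hot(train$labels, cfg$n_classes) else NULL

  theta <- flatten_tree(net$params)
  opt <- adam_init(length(theta))
  hist <- vector("list", control$max_epochs)
  val_losses <- numeric(0)
  best <- Inf; best_epoch <- 0L; wait <- 0L
  best_params <- net$params; best_state <- net$state
  stop_epoch <- control$max_epochs

  for (epoch in seq_len(control$max_epochs)) {
    perm <- sample.int(N)
    tr_rec <- 0; tr_cls <- 0; tr_tot <- 0
    for (lo in seq.int(1L, N, by = control$batch_size)) {
      hi <- min(lo + control$batch_size - 1L, N)
      idx <- perm[lo:hi]
      nb <- length(idx)
      xb <- x_all[idx, , , drop = FALSE]
      fw <- net_forward(net, xb, training = TRUE)
      net$state <- fw$state
      d_recon <- NULL; d_logits <- NULL
      rec_l <- 0; cls_l <- 0
      if (g$has_dec) {
        r <- fw$out$reconstruction - xb
        rec_l <- huber_loss(r, control$huber_delta)
        d_recon <- (w[1] / length(r)) * huber_grad(r, control$huber_delta)
      }
      if (g$has_cls) {
        yb <- y_all[idx, , drop = FALSE]
        cls_l <- cross_entropy_loss(train$labels[idx], fw$out$class_probs)
        d_logits <- (w[2] / nb) * (fw$out$class_probs - yb)
      }
      total_l <- w[1] * rec_l + w[2] * cls_l
      if (!is.finite(total_l))
        stop(sprintf(paste0("non-finite loss at epoch %d (reconstruction=%g, ",
                            "classification=%g); try a lower learning rate"),
                     epoch, rec_l, cls_l))
      grads <- net_backward(net, fw$cache, d_recon, d_logits)
      st <- adam_step(opt, theta, flatten_tree(grads), control$learning_rate)
      opt <- st$opt; theta <- st$theta
      net$params <- unflatten_tree(theta, net$params)
      tr_rec <- tr_rec + rec_l * nb; tr_cls <- tr_cls + cls_l * nb
      tr_tot <- tr_tot + total_l * nb
    }

    vl <- eval_batch_loss(net, val, control)
    val_losses <- c(val_losses, vl$total)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_total = tr_tot / N, train_reconstruction = tr_rec / N,
      train_classification = tr_cls / N, val_total = vl$total,
      val_reconstruction = vl$reconstruction,
      val_classification = vl$classification, val_accuracy = vl$accuracy)
    if (verbose)
      cat(sprintf("epoch %3d  train %.5f  val %.5f  val_acc %s\n", epoch,
                  tr_tot / N, vl$total,
                  if (is.na(vl$accuracy)) "-" else sprintf("%.3f", vl$accuracy)))

    if (epoch == 1L || vl$total < best - control$min_delta) {
      best <- vl$total; best_epoch <- epoch
      best_params <- net$params; best_state <- net$state
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) { stop_epoch <- epoch; break }
    }
    stop_epoch <- epoch
  }

  if (control$restore_best) {
    net$params <- best_params
    net$state <- best_state
  }
  history <- structure(list(epochs = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                            stop_epoch = stop_epoch, best_epoch = best_epoch,
                            best_val_loss = best),
                       class = "train_history")
  list(net = net, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epoch(s), best epoch %d (val loss %.6f)\n",
              x$stop_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}
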