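#' Network configuration
#'
#' Declarative description of the four network variants, sufficient to
#' rebuild the network and count its trainable parameters:
#' \describe{
#'   \item{AE}{unsupervised multi-channel asymmetric auto-encoder: one
#'     encoder per channel, a fusion dense layer shaping the latent space,
#'     one decoder per channel plus an aggregation convolution.}
#'   \item{STL}{supervised single-task baseline: the encoder block and fusion
#'     layer with a softmax classification head, no decoder.}
#'   \item{MCAE}{the multi-task model: decoders and classification head share
#'     one latent space.}
#'   \item{CAE}{classical shared auto-encoder: a single encoder over the
#'     C-channel input treated as one multivariate stream, and a single
#'     decoder emitting all C channels, plus the classification head.}
#' }
#' Each encoder is a batch-normalization layer followed by four repetitions
#' of (1-D convolution, activation, max-pool factor 2), so the latent
#' temporal length is `window_length / 16`. Each decoder is a
#' batch-normalization layer followed by four stride-2 transposed
#' convolutions (linear on the last stage).
#'
#' @param n_channels number of input channels C.
#' @param window_length window length T in samples; multiple of 16.
#' @param n_classes number of activity classes K (required for variants with
#'   a classification head).
#' @param variant one of `"AE"`, `"STL"`, `"MCAE"`, `"CAE"`.
#' @param conv_filters encoder filter counts per stage (length 4).
#' @param kernel_size odd convolution kernel width.
#' @param latent_channels latent feature depth per timestep.
#' @param activation activation name, see [activation_value()].
#' @param fusion `"timestep"` (default) applies the fusion dense layer
#'   identically at every latent timestep; `"flatten"` fuses the fully
#'   flattened concatenation instead.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_channels, window_length, n_classes = NULL,
                         variant = c("MCAE", "AE", "STL", "CAE"),
                         conv_filters = c(8L, 8L, 8L, 8L), kernel_size = 3L,
                         latent_channels = 8L, activation = "selu",
                         fusion = c("timestep", "flatten")) {
  variant <- match.arg(variant)
  fusion <- match.arg(fusion)
  n_channels <- as.integer(n_channels)
  window_length <- as.integer(window_length)
  kernel_size <- as.integer(kernel_size)
  conv_filters <- as.integer(conv_filters)
  latent_channels <- as.integer(latent_channels)
  if (n_channels < 1L) stop("`n_channels` must be >= 1")
  if (length(conv_filters) != 4L) stop("`conv_filters` must have length 4 (one per stage)")
  if (window_length %% 16L != 0L)
    stop("`window_length` must be divisible by 16 (four pooling stages of factor 2)")
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  if (latent_channels < 1L) stop("`latent_channels` must be >= 1")
  if (!activation %in% names(activation_registry))
    stop(sprintf("unknown activation '%s'; available: %s", activation,
                 paste(names(activation_registry), collapse = ", ")))
  if (variant %in% c("STL", "MCAE", "CAE")) {
    if (is.null(n_classes) || n_classes < 2L)
      stop(sprintf("variant %s has a classification head and needs n_classes >= 2", variant))
    n_classes <- as.integer(n_classes)
  }
  structure(list(n_channels = n_channels, window_length = window_length,
                 n_classes = n_classes, variant = variant,
                 conv_filters = conv_filters, kernel_size = kernel_size,
                 pool_factor = 2L, n_stages = 4L,
                 latent_channels = latent_channels, activation = activation,
                 fusion = fusion),
            class = "model_config")
}

cfg_geometry <- function(cfg) {
  f_last <- cfg$conv_filters[cfg$n_stages]
  list(
    t_latent = cfg$window_length %/% 16L,
    f_last = f_last,
    n_enc = if (cfg$variant == "CAE") 1L else cfg$n_channels,
    enc_in = if (cfg$variant == "CAE") cfg$n_channels else 1L,
    n_dec = if (cfg$variant == "STL") 0L else if (cfg$variant == "CAE") 1L else cfg$n_channels,
    dec_out = if (cfg$variant == "CAE") cfg$n_channels else 1L,
    has_cls = cfg$variant %in% c("STL", "MCAE", "CAE"),
    has_dec = cfg$variant %in% c("AE", "MCAE", "CAE"),
    fus_in = if (cfg$fusion == "timestep") {
      (if (cfg$variant == "CAE") 1L else cfg$n_channels) * f_last
    } else {
      (cfg$window_length %/% 16L) *
        (if (cfg$variant == "CAE") 1L else cfg$n_channels) * f_last
    },
    fus_out = if (cfg$fusion == "timestep") cfg$latent_channels
              else (cfg$window_length %/% 16L) * cfg$latent_channels,
    flat_latent = (cfg$window_length %/% 16L) * cfg$latent_channels
  )
}

init_conv <- function(k, f_in, f_out) {
  list(W = array(stats::rnorm(k * f_in * f_out, sd = 1 / sqrt(k * f_in)),
                 c(k, f_in, f_out)),
       b = numeric(f_out))
}

init_dense <- function(f_in, f_out) {
  list(W = matrix(stats::rnorm(f_in * f_out, sd = 1 / sqrt(f_in)), f_in, f_out),
       b = numeric(f_out))
}

init_bn <- function(f) list(gamma = rep(1, f), beta = numeric(f))

bn_state0 <- function(f) list(mean = numeric(f), var = rep(1, f))

#' Assemble a network from its configuration
#'
#' Initializes all trainable parameters (fan-in-scaled normal weights, zero
#' biases, unit batch-norm scales) and builds the layer-by-layer
#' [network_description()] audit table.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer; when given, parameter initialization is run
#'   under this seed (the caller's RNG state is restored afterwards).
#' @return an object of class `mcae_net` with elements `config`, `params`
#'   (nested list of trainable arrays), `state` (batch-norm running moments)
#'   and `description` (a data frame).
#' @export
assemble <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  g <- cfg_geometry(cfg)
  k <- cfg$kernel_size
  params <- list()
  state <- list()

  params$enc <- vector("list", g$n_enc)
  state$enc <- vector("list", g$n_enc)
  for (e in seq_len(g$n_enc)) {
    convs <- vector("list", cfg$n_stages)
    f_in <- g$enc_in
    for (s in seq_len(cfg$n_stages)) {
      convs[[s]] <- init_conv(k, f_in, cfg$conv_filters[s])
      f_in <- cfg$conv_filters[s]
    }
    params$enc[[e]] <- list(bn = init_bn(g$enc_in), conv = convs)
    state$enc[[e]] <- bn_state0(g$enc_in)
  }

  params$fus <- init_dense(g$fus_in, g$fus_out)

  if (g$has_dec) {
    params$dec <- vector("list", g$n_dec)
    state$dec <- vector("list", g$n_dec)
    dec_filters <- c(rep(g$f_last, cfg$n_stages - 1L), g$dec_out)
    for (d in seq_len(g$n_dec)) {
      deconvs <- vector("list", cfg$n_stages)
      f_in <- cfg$latent_channels
      for (s in seq_len(cfg$n_stages)) {
        deconvs[[s]] <- init_conv(k, f_in, dec_filters[s])
        f_in <- dec_filters[s]
      }
      params$dec[[d]] <- list(bn = init_bn(cfg$latent_channels), deconv = deconvs)
      state$dec[[d]] <- bn_state0(cfg$latent_channels)
    }
    params$agg <- init_conv(k, cfg$n_channels, cfg$n_channels)
  }

  if (g$has_cls) {
    params$cls <- c(list(bn = init_bn(g$flat_latent)),
                    init_dense(g$flat_latent, cfg$n_classes))
    state$cls <- bn_state0(g$flat_latent)
  }

  net <- structure(list(config = cfg, params = params, state = state),
                   class = "mcae_net")
  net$description <- network_description(net)
  net
}

#' Layer-by-layer audit table of a network
#'
#' One row per layer instance (including parameter-free pooling and
#' activation layers) with input/output shapes and trainable-parameter
#' counts; the `total_trainable` attribute is the column sum and always
#' equals [count_trainable_parameters()].
#'
#' @param net an `mcae_net` from [assemble()].
#' @return a data frame with attribute `total_trainable`.
#' @export
network_description <- function(net) {
  cfg <- net$config
  g <- cfg_geometry(cfg)
  T <- cfg$window_length
  rows <- list()
  add <- function(name, kind, ins, outs, n)
    rows[[length(rows) + 1L]] <<- data.frame(layer = name, kind = kind,
                                             input_shape = ins,
                                             output_shape = outs,
                                             n_params = n)
  sh <- function(t, f) sprintf("(%d, %d)", t, f)
  for (e in seq_len(g$n_enc)) {
    p <- net$params$enc[[e]]
    add(sprintf("enc%d_bn", e), "batch_norm", sh(T, g$enc_in), sh(T, g$enc_in),
        length(p$bn$gamma) * 2L)
    t <- T; f_in <- g$enc_in
    for (s in seq_len(cfg$n_stages)) {
      f_out <- cfg$conv_filters[s]
      add(sprintf("enc%d_conv%d", e, s), "conv1d", sh(t, f_in), sh(t, f_out),
          length(p$conv[[s]]$W) + length(p$conv[[s]]$b))
      add(sprintf("enc%d_pool%d", e, s), "max_pool", sh(t, f_out), sh(t %/% 2L, f_out), 0L)
      t <- t %/% 2L; f_in <- f_out
    }
  }
  fus_in_sh <- if (cfg$fusion == "timestep") sh(g$t_latent, g$n_enc * g$f_last)
               else sprintf("(%d)", g$fus_in)
  add("fusion_dense", "dense", fus_in_sh, sh(g$t_latent, cfg$latent_channels),
      length(net$params$fus$W) + length(net$params$fus$b))
  if (g$has_dec) {
    dec_filters <- c(rep(g$f_last, cfg$n_stages - 1L), g$dec_out)
    for (d in seq_len(g$n_dec)) {
      p <- net$params$dec[[d]]
      add(sprintf("dec%d_bn", d), "batch_norm", sh(g$t_latent, cfg$latent_channels),
          sh(g$t_latent, cfg$latent_channels), length(p$bn$gamma) * 2L)
      t <- g$t_latent; f_in <- cfg$latent_channels
      for (s in seq_len(cfg$n_stages)) {
        add(sprintf("dec%d_deconv%d", d, s), "deconv1d", sh(t, f_in),
            sh(t * 2L, dec_filters[s]),
            length(p$deconv[[s]]$W) + length(p$deconv[[s]]$b))
        t <- t * 2L; f_in <- dec_filters[s]
      }
    }
    add("aggregate_conv", "conv1d", sh(T, cfg$n_channels), sh(T, cfg$n_channels),
        length(net$params$agg$W) + length(net$params$agg$b))
  }
  if (g$has_cls) {
    add("cls_flatten", "flatten", sh(g$t_latent, cfg$latent_channels),
        sprintf("(%d)", g$flat_latent), 0L)
    add("cls_bn", "batch_norm", sprintf("(%d)", g$flat_latent),
        sprintf("(%d)", g$flat_latent), length(net$params$cls$bn$gamma) * 2L)
    add("cls_dense", "dense+softmax", sprintf("(%d)", g$flat_latent),
        sprintf("(%d)", cfg$n_classes),
        length(net$params$cls$W) + length(net$params$cls$b))
  }
  out <- do.call(rbind, rows)
  attr(out, "total_trainable") <- sum(out$n_params)
  out
}

#' Count trainable parameters
#'
#' Batch-norm layers contribute two trainable values (scale, shift) per
#' feature; running moments are not trainable and are not counted.
#'
#' @param model an `mcae_net` or a fitted [mcae()] object.
#' @return integer total.
#' @export
count_trainable_parameters <- function(model) {
  if (inherits(model, "mcae")) model <- model$net
  stopifnot(inherits(model, "mcae_net"))
  length(flatten_tree(model$params))
}

flatten_tree <- function(tree) unlist(tree, use.names = FALSE)

unflatten_tree <- function(vec, skeleton) {
  i <- 0L
  rec <- function(s) {
    if (is.numeric(s)) {
      n <- length(s)
      out <- vec[(i + 1L):(i + n)]
      i <<- i + n
      dim(out) <- dim(s)
      out
    } else lapply(s, rec)
  }
  rec(skeleton)
}

# Full forward pass. x: (N, T, C) array. Returns outputs, the (possibly
# updated) batch-norm state, and layer caches for the backward pass.
net_forward <- function(net, x, training = FALSE) {
  cfg <- net$config
  g <- cfg_geometry(cfg)
  N <- dim(x)[1]; T <- dim(x)[2]
  if (dim(x)[3] != cfg$n_channels)
    stop(sprintf("channel axis mismatch: input has %d channels, config expects %d",
                 dim(x)[3], cfg$n_channels))
  if (T != cfg$window_length)
    stop(sprintf("time axis mismatch: input windows have %d timesteps, config expects %d",
                 T, cfg$window_length))
  act <- cfg$activation
  cache <- list(enc = vector("list", g$n_enc))
  enc_out <- vector("list", g$n_enc)
  for (e in seq_len(g$n_enc)) {
    xe <- if (cfg$variant == "CAE") x else x[, , e, drop = FALSE]
    p <- net$params$enc[[e]]
    bn <- bn_fw(as_mat(xe), p$bn$gamma, p$bn$beta, net$state$enc[[e]], training)
    net$state$enc[[e]] <- bn$state
    h <- as_arr(bn$y, N, T)
    stages <- vector("list", cfg$n_stages)
    for (s in seq_len(cfg$n_stages)) {
      cv <- conv1d_fw(h, p$conv[[s]]$W, p$conv[[s]]$b)
      a <- activation_value(act, cv$y)
      pl <- maxpool2_fw(a)
      stages[[s]] <- list(conv = cv$cache, pre = cv$y, act = a, pool = pl$cache)
      h <- pl$y
    }
    cache$enc[[e]] <- list(bn = bn$cache, stages = stages)
    enc_out[[e]] <- h
  }
  concat <- array(0, c(N, g$t_latent, g$n_enc * g$f_last))
  for (e in seq_len(g$n_enc))
    concat[, , ((e - 1L) * g$f_last + 1L):(e * g$f_last)] <- enc_out[[e]]
  if (cfg$fusion == "timestep") {
    fu <- dense_fw(as_mat(concat), net$params$fus$W, net$params$fus$b)
    latent <- as_arr(fu$y, N, g$t_latent)
  } else {
    cm <- concat; dim(cm) <- c(N, g$fus_in)
    fu <- dense_fw(cm, net$params$fus$W, net$params$fus$b)
    latent <- fu$y; dim(latent) <- c(N, g$t_latent, cfg$latent_channels)
  }
  cache$fus <- fu$cache
  out <- list(latent = latent)

  if (g$has_dec) {
    streams <- array(0, c(N, T, cfg$n_channels))
    cache$dec <- vector("list", g$n_dec)
    lat_mat <- latent; dim(lat_mat) <- c(N * g$t_latent, cfg$latent_channels)
    for (d in seq_len(g$n_dec)) {
      p <- net$params$dec[[d]]
      bn <- bn_fw(lat_mat, p$bn$gamma, p$bn$beta, net$state$dec[[d]], training)
      net$state$dec[[d]] <- bn$state
      h <- as_arr(bn$y, N, g$t_latent)
      stages <- vector("list", cfg$n_stages)
      for (s in seq_len(cfg$n_stages)) {
        dc <- deconv2_fw(h, p$deconv[[s]]$W, p$deconv[[s]]$b)
        if (s < cfg$n_stages) {            # linear final stage
          a <- activation_value(act, dc$y)
          stages[[s]] <- list(deconv = dc$cache, pre = dc$y, act = a)
          h <- a
        } else {
          stages[[s]] <- list(deconv = dc$cache)
          h <- dc$y
        }
      }
      cache$dec[[d]] <- list(bn = bn$cache, stages = stages)
      if (cfg$variant == "CAE") streams <- h
      else streams[, , d] <- h[, , 1L]
    }
    ag <- conv1d_fw(streams, net$params$agg$W, net$params$agg$b)
    cache$agg <- ag$cache
    out$reconstruction <- ag$y
  }

  if (g$has_cls) {
    flat <- latent; dim(flat) <- c(N, g$flat_latent)
    p <- net$params$cls
    bn <- bn_fw(flat, p$bn$gamma, p$bn$beta, net$state$cls, training)
    net$state$cls <- bn$state
    dn <- dense_fw(bn$y, p$W, p$b)
    out$logits <- dn$y
    out$class_probs <- softmax_rows(dn$y)
    cache$cls <- list(bn = bn$cache, dense = dn$cache)
  }

  list(out = out, cache = cache, state = net$state)
}

# Backward pass: d_recon is dLoss/dReconstruction (N, T, C) or NULL;
# d_logits is dLoss/dLogits (N, K) or NULL. Returns gradients shaped like
# net$params.
net_backward <- function(net, cache, d_recon = NULL, d_logits = NULL) {
  cfg <- net$config
  g <- cfg_geometry(cfg)
  act <- cfg$activation
  grads <- list()
  d_latent <- NULL
  N <- NULL

  if (!is.null(d_recon)) {
    N <- dim(d_recon)[1]
    ag <- conv1d_bw(d_recon, cache$agg)
    grads$agg <- list(W = ag$dW, b = ag$db)
    grads$dec <- vector("list", g$n_dec)
    for (d in seq_len(g$n_dec)) {
      dh <- if (cfg$variant == "CAE") ag$dx
            else {
              tmp <- array(0, c(N, cfg$window_length, 1L))
              tmp[, , 1L] <- ag$dx[, , d]
              tmp
            }
      stages <- cache$dec[[d]]$stages
      for (s in rev(seq_len(cfg$n_stages))) {
        if (s < cfg$n_stages)
          dh <- dh * activation_grad(act, stages[[s]]$pre, stages[[s]]$act)
        bwd <- deconv2_bw(dh, stages[[s]]$deconv)
        grads$dec[[d]]$deconv[[s]] <- list(W = bwd$dW, b = bwd$db)
        dh <- bwd$dx
      }
      dh_mat <- dh; dim(dh_mat) <- c(N * g$t_latent, cfg$latent_channels)
      bnb <- bn_bw(dh_mat, cache$dec[[d]]$bn)
      grads$dec[[d]]$bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
      dl <- bnb$dx; dim(dl) <- c(N, g$t_latent, cfg$latent_channels)
      d_latent <- if (is.null(d_latent)) dl else d_latent + dl
    }
    # reorder grads$dec fields to match params layout (bn first, then deconv)
    for (d in seq_len(g$n_dec))
      grads$dec[[d]] <- list(bn = grads$dec[[d]]$bn, deconv = grads$dec[[d]]$deconv)
  }

  if (!is.null(d_logits)) {
    N <- dim(d_logits)[1]
    dn <- dense_bw(d_logits, cache$cls$dense)
    bnb <- bn_bw(dn$dx, cache$cls$bn)
    grads$cls <- list(bn = list(gamma = bnb$dgamma, beta = bnb$dbeta),
                      W = dn$dW, b = dn$db)
    dl <- bnb$dx; dim(dl) <- c(N, g$t_latent, cfg$latent_channels)
    d_latent <- if (is.null(d_latent)) dl else d_latent + dl
  }

  if (is.null(d_latent))
    stop("no head gradient supplied to net_backward")

  if (cfg$fusion == "timestep") {
    dlm <- d_latent; dim(dlm) <- c(N * g$t_latent, cfg$latent_channels)
    fu <- dense_bw(dlm, cache$fus)
    d_concat <- as_arr(fu$dx, N, g$t_latent)
  } else {
    dlm <- d_latent; dim(dlm) <- c(N, g$fus_out)
    fu <- dense_bw(dlm, cache$fus)
    d_concat <- fu$dx; dim(d_concat) <- c(N, g$t_latent, g$fus_in %/% g$t_latent)
  }
  grads$fus <- list(W = fu$dW, b = fu$db)

  grads$enc <- vector("list", g$n_enc)
  for (e in seq_len(g$n_enc)) {
    dh <- d_concat[, , ((e - 1L) * g$f_last + 1L):(e * g$f_last), drop = FALSE]
    stages <- cache$enc[[e]]$stages
    conv_g <- vector("list", cfg$n_stages)
    for (s in rev(seq_len(cfg$n_stages))) {
      dh <- maxpool2_bw(dh, stages[[s]]$pool)
      dh <- dh * activation_grad(act, stages[[s]]$pre, stages[[s]]$act)
      bwd <- conv1d_bw(dh, stages[[s]]$conv)
      conv_g[[s]] <- list(W = bwd$dW, b = bwd$db)
      dh <- bwd$dx
    }
    dh_mat <- as_mat(dh)
    bnb <- bn_bw(dh_mat, cache$enc[[e]]$bn)
    grads$enc[[e]] <- list(bn = list(gamma = bnb$dgamma, beta = bnb$dbeta),
                           conv = conv_g)
  }

  # match params ordering: enc, fus, dec, agg, cls
  out <- list(enc = grads$enc, fus = grads$fus)
  if (!is.null(grads$dec)) { out$dec <- grads$dec; out$agg <- grads$agg }
  if (!is.null(grads$cls)) out$cls <- grads$cls
  out
}

#' Run a forward pass on a window batch
#'
#' Inference-mode forward pass (batch-norm uses running moments, so repeated
#' calls with the same weights and input are bitwise identical). Returns the
#' model outputs present for the variant: the reconstruction (N x C x T; AE,
#' MCAE, CAE), class probabilities (N x K, rows summing to 1; STL, MCAE,
#' CAE) and the shared latent tensor (N x T/16 x latent_channels; always).
#'
#' @param model an `mcae_net` or fitted [mcae()] object.
#' @param batch a standardized [window_batch()].
#' @return a list with elements `latent`, and where present `reconstruction`
#'   and `class_probs`.
#' @export
model_forward <- function(model, batch) {
  if (inherits(model, "mcae")) model <- model$net
  stopifnot(inherits(model, "mcae_net"), inherits(batch, "window_batch"))
  x <- aperm(batch$windows, c(1, 3, 2))
  fw <- net_forward(model, x, training = FALSE)
  out <- list(latent = fw$out$latent)
  if (!is.null(fw$out$reconstruction))
    out$reconstruction <- aperm(fw$out$reconstruction, c(1, 3, 2))
  if (!is.null(fw$out$class_probs)) out$class_probs <- fw$out$class_probs
  out
}

#' @export
print.mcae_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mcae_net> variant=%s  C=%d  T=%d  latent=%dx%d  activation=%s\n",
              cfg$variant, cfg$n_channels, cfg$window_length,
              cfg$window_length %/% 16L, cfg$latent_channels, cfg$activation))
  if (!is.null(cfg$n_classes)) cat(sprintf("  classes: %d\n", cfg$n_classes))
  cat(sprintf("  trainable parameters: %d\n", count_trainable_parameters(x)))
  invisible(x)
}
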