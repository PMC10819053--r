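test_that("activation registry matches the published definitions", {
  expect_equal(activation_value("relu", c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(activation_value("selu", 0), 0)
  expect_equal(activation_value("swish", 0), 0)
  expect_equal(activation_value("selu", 1), 1.0507009873554805)
  expect_equal(activation_value("elu", -1), exp(-1) - 1)
  # selu saturates at -lambda*alpha
  expect_equal(activation_value("selu", -50),
               -1.0507009873554805 * 1.6732632423543772, tolerance = 1e-12)
  expect_equal(activation_value("swish", 2), 2 / (1 + exp(-2)))
  expect_error(activation_value("tanhx", 1), "relu")
})

# Independent layer-by-layer arithmetic for every variant, written from the
# architecture definition (not from the package's counting code).
oracle_params <- function(variant, C, T, K, f = 8, k = 3, Dl = 8) {
  enc_ch <- function(fin) 2 * fin + (k * fin * f + f) + 3 * (k * f * f + f)
  dec_ch <- function(out) 2 * Dl + (k * Dl * f + f) + 2 * (k * f * f + f) +
    (k * f * out + out)
  flat <- (T / 16) * Dl
  cls <- 2 * flat + flat * K + K
  agg <- k * C * C + C
  switch(variant,
    MCAE = C * enc_ch(1) + (C * f * Dl + Dl) + C * dec_ch(1) + agg + cls,
    AE   = C * enc_ch(1) + (C * f * Dl + Dl) + C * dec_ch(1) + agg,
    STL  = C * enc_ch(1) + (C * f * Dl + Dl) + cls,
    CAE  = enc_ch(C) + (f * Dl + Dl) + dec_ch(C) + agg + cls)
}

test_that("parameter counts equal independent layer-by-layer arithmetic", {
  for (C in c(1L, 3L, 6L)) {
    for (v in c("MCAE", "AE", "STL", "CAE")) {
      cfg <- model_config(C, 128, if (v == "AE") NULL else 6, v)
      net <- assemble(cfg, seed = 1)
      expect_equal(count_trainable_parameters(net), oracle_params(v, C, 128, 6),
                   info = sprintf("%s C=%d", v, C))
      # description table total always matches the flattened count
      expect_equal(attr(net$description, "total_trainable"),
                   count_trainable_parameters(net))
    }
  }
})

test_that("individual layer counts match closed-form formulas", {
  net <- assemble(model_config(6, 128, 6, "MCAE"), seed = 1)
  d <- net$description
  get <- function(nm) d$n_params[d$layer == nm]
  expect_equal(get("enc1_conv1"), 1 * 8 * 3 + 8)      # 32
  expect_equal(get("enc1_conv2"), 8 * 8 * 3 + 8)      # 200
  expect_equal(get("fusion_dense"), 48 * 8 + 8)       # 392
  expect_equal(get("aggregate_conv"), 6 * 6 * 3 + 6)  # 114
  expect_equal(get("cls_dense"), 64 * 6 + 6)          # 390
  expect_equal(get("dec1_bn"), 16)                    # 2 per feature
  # a plain dense layer: 384 -> 64
  dn <- mcae:::init_dense(384, 64)
  expect_equal(length(dn$W) + length(dn$b), 24640)
})

test_that("encoder compresses 16x and the decoder restores the input shape", {
  for (T in c(16L, 128L, 496L, 512L)) {
    cfg <- tiny_model("MCAE", window_length = T)
    net <- assemble(cfg, seed = 1)
    b <- window_batch(array(rnorm(2 * 2 * T), c(2, 2, T)), c(0L, 1L),
                      c("a", "b"), 1L)
    out <- model_forward(net, b)
    expect_equal(dim(out$latent), c(2, T / 16, 2))
    expect_equal(dim(out$reconstruction), dim(b$windows))
  }
})

test_that("STL shares the MCAE latent geometry and has no deconvolutions", {
  stl <- assemble(tiny_model("STL"), seed = 1)
  mt <- assemble(tiny_model("MCAE"), seed = 1)
  expect_false(any(stl$description$kind == "deconv1d"))
  b <- window_batch(array(rnorm(3 * 2 * 16), c(3, 2, 16)), c(0L, 1L, 0L),
                    rep("s", 3), 1L)
  expect_equal(dim(model_forward(stl, b)$latent), dim(model_forward(mt, b)$latent))
})

test_that("CAE is much smaller than MCAE for the same configuration", {
  mcae_n <- count_trainable_parameters(assemble(model_config(6, 128, 6, "MCAE"), seed = 1))
  cae_n <- count_trainable_parameters(assemble(model_config(6, 128, 6, "CAE"), seed = 1))
  expect_lt(cae_n, mcae_n / 3)
})

test_that("softmax rows are shift-invariant and sum to one", {
  p <- mcae:::softmax_rows(matrix(c(3, 3, 3), 1))
  expect_equal(as.numeric(p), rep(1 / 3, 3))
  logits <- matrix(rnorm(12), 3, 4)
  p1 <- mcae:::softmax_rows(logits)
  p2 <- mcae:::softmax_rows(logits + 100)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-6)
  # extreme logits stay finite
  expect_false(any(!is.finite(mcae:::softmax_rows(matrix(c(1e4, -1e4), 1)))))
})

test_that("forward pass is deterministic in inference mode", {
  net <- assemble(tiny_model("MCAE"), seed = 2)
  b <- window_batch(array(rnorm(4 * 2 * 16), c(4, 2, 16)), rep(0:1, 2),
                    rep("s", 4), 1L)
  o1 <- model_forward(net, b)
  o2 <- model_forward(net, b)
  expect_identical(o1$latent, o2$latent)
  expect_identical(o1$reconstruction, o2$reconstruction)
  expect_equal(rowSums(o1$class_probs), rep(1, 4), tolerance = 1e-6)
})

test_that("forward pass validates input shape", {
  net <- assemble(tiny_model("MCAE"), seed = 1)
  bad_ch <- window_batch(array(rnorm(2 * 3 * 16), c(2, 3, 16)), c(0L, 1L),
                         c("a", "b"), 1L)
  expect_error(model_forward(net, bad_ch), "channel")
  bad_t <- window_batch(array(rnorm(2 * 2 * 32), c(2, 2, 32)), c(0L, 1L),
                        c("a", "b"), 1L)
  expect_error(model_forward(net, bad_t), "time")
})

test_that("analytic gradients match numerical differentiation", {
  for (v in c("MCAE", "AE", "STL", "CAE")) {
    set.seed(5)
    cfg <- model_config(2, 32, if (v == "AE") NULL else 3, v,
                        conv_filters = c(2, 2, 2, 2), latent_channels = 2,
                        activation = "swish")
    net <- assemble(cfg, seed = 4)
    N <- 3
    x <- array(rnorm(N * 32 * 2), c(N, 32, 2))
    labels <- c(0L, 1L, 2L)
    y <- mcae:::one_hot(labels, 3)
    has_dec <- v != "STL"; has_cls <- v != "AE"
    loss_fn <- function(nn) {
      fw <- mcae:::net_forward(nn, x, training = TRUE)
      l <- 0
      if (has_dec) l <- l + huber_loss(fw$out$reconstruction - x, 1)
      if (has_cls) l <- l + cross_entropy_loss(labels, fw$out$class_probs)
      l
    }
    fw <- mcae:::net_forward(net, x, training = TRUE)
    d_recon <- if (has_dec) mcae:::huber_grad(fw$out$reconstruction - x, 1) / length(x)
    d_logits <- if (has_cls) (fw$out$class_probs - y) / N
    ga <- mcae:::flatten_tree(mcae:::net_backward(net, fw$cache, d_recon, d_logits))
    theta <- mcae:::flatten_tree(net$params)
    idx <- sort(sample(length(theta), 40))
    eps <- 1e-5
    gn <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      np <- net; np$params <- mcae:::unflatten_tree(tp, net$params)
      tm <- theta; tm[i] <- tm[i] - eps
      nm <- net; nm$params <- mcae:::unflatten_tree(tm, net$params)
      (loss_fn(np) - loss_fn(nm)) / (2 * eps)
    }, 1)
    err <- abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx]))
    expect_lt(max(err), 1e-3)
  }
})
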