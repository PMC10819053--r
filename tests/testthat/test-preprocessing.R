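test_that("denoise passes DC and removes isolated spikes", {
  const <- raw_recording(matrix(5, 1, 200), 50)
  out <- denoise(const, filter_config())
  expect_equal(out$signal, const$signal, tolerance = 1e-8)

  # median stage alone (low-pass skipped above Nyquist, with a warning)
  imp <- raw_recording(matrix(c(0, 0, 10, 0, 0), 1, 5), 50)
  expect_warning(out <- denoise(imp, filter_config(median_kernel = 3,
                                                   butter_cutoff = 40)),
                 "Nyquist")
  expect_equal(as.numeric(out$signal), rep(0, 5))
})

test_that("low-pass attenuation matches the designed magnitude response", {
  fs <- 50; f0 <- 24
  t <- seq(0, 20, by = 1 / fs)
  rec <- raw_recording(matrix(sin(2 * pi * f0 * t), 1), fs)
  mid <- seq(round(0.2 * length(t)), round(0.8 * length(t)))
  ratio_for <- function(order, cutoff) {
    out <- denoise(rec, filter_config(median_kernel = 1, butter_order = order,
                                      butter_cutoff = cutoff))
    sd(out$signal[1, mid]) / sd(rec$signal[1, mid])
  }
  # forward-backward filtering squares the designed digital filter's gain
  theory <- function(order, cutoff)
    lowpass_gain(filter_config(butter_order = order, butter_cutoff = cutoff),
                 f0, fs)^2
  expect_equal(ratio_for(3, 20), theory(3, 20), tolerance = 0.05)
  expect_equal(ratio_for(4, 18), theory(4, 18), tolerance = 0.05)
  # the default design leaves less than 10% of a 24 Hz tone's amplitude
  expect_lt(ratio_for(3, 20), 0.10)
})

test_that("denoise rejects non-finite samples with location info", {
  sig <- matrix(rnorm(100), 2, 50)
  sig[2, 17] <- NA
  expect_error(denoise(raw_recording(sig, 50)), "channel 2.*index 17")
})

test_that("window_samples rounds down to multiples of 16", {
  expect_identical(window_samples(2.56, 50), 128L)
  expect_identical(window_samples(5.12, 100), 512L)
  expect_identical(window_samples(5, 100), 496L)
  expect_identical(window_samples(10, 100), 992L)
  expect_error(window_samples(0.2, 50), "16")
})

test_that("segment counts windows and applies the majority-label rule", {
  rec <- raw_recording(matrix(rnorm(128), 1), 50, labels = rep(0L, 128))
  expect_equal(mcae:::n_windows(segment(rec, 128, 64)), 1L)

  rec2 <- raw_recording(matrix(rnorm(1000), 1), 50, labels = rep(0L, 1000))
  expect_equal(mcae:::n_windows(segment(rec2, 128, 64)), floor((1000 - 128) / 64) + 1)

  # majority 65/63 -> labeled by the majority class
  maj <- raw_recording(matrix(rnorm(128), 1), 50,
                       labels = c(rep(0L, 65), rep(1L, 63)))
  b <- segment(maj, 128, 64)
  expect_equal(b$labels, 0L)
  # exact 64/64 tie -> dropped
  tie <- raw_recording(matrix(rnorm(128), 1), 50,
                       labels = c(rep(0L, 64), rep(1L, 64)))
  expect_null(segment(tie, 128, 64))
  # unlabeled majority -> dropped
  unl <- raw_recording(matrix(rnorm(128), 1), 50,
                       labels = c(rep(-1L, 70), rep(1L, 58)))
  expect_null(segment(unl, 128, 64))

  expect_error(segment(rec2, 100, 50), "divisible by 16")
})

test_that("segment count matches brute-force enumeration of window starts", {
  set.seed(11)
  for (i in 1:20) {
    T <- 16L * sample(1:4, 1)
    L <- T + sample(0:200, 1)
    stride <- sample(1:80, 1)
    rec <- raw_recording(matrix(rnorm(L), 1), 50, labels = rep(0L, L))
    brute <- sum(seq(0L, L, by = 1L) + T <= L & seq(0L, L, by = 1L) %% stride == 0)
    expect_equal(mcae:::n_windows(segment(rec, T, stride)), floor((L - T) / stride) + 1)
    expect_equal(mcae:::n_windows(segment(rec, T, stride)), brute)
  }
})

test_that("standardizer computes pooled per-channel moments and freezes them", {
  w <- array(0, c(4, 2, 16))
  w[, 1, ] <- 7                                   # constant channel
  w[, 2, ] <- rep(c(-1, 1), length.out = 4 * 16)  # balanced +-1
  b <- window_batch(w, rep(0L, 4), rep("s", 4), 8L)
  st <- fit_standardizer(b)
  expect_equal(st$mean, c(7, 0))
  expect_equal(st$std, c(0, 1))
  expect_identical(st, fit_standardizer(b))       # deterministic

  z <- standardize(b, st)
  expect_true(all(z$windows[, 1, ] == 0))         # epsilon guard on std 0
  expect_lt(abs(mean(z$windows[, 2, ])), 1e-6)
  expect_lt(abs(sqrt(mean((z$windows[, 2, ] - mean(z$windows[, 2, ]))^2)) - 1), 1e-6)

  # held-out data transformed with frozen training stats keeps its shift
  w2 <- w; w2[, 2, ] <- w2[, 2, ] + 3
  z2 <- standardize(window_batch(w2, rep(0L, 4), rep("s", 4), 8L), st)
  expect_equal(mean(z2$windows[, 2, ]), 3, tolerance = 1e-8)

  expect_error(standardize(window_batch(array(0, c(2, 3, 16)), rep(0L, 2),
                                        rep("s", 2), 8L), st),
               "channel mismatch")
})

test_that("standardization is idempotent under refitted stats", {
  splits <- tiny_splits()
  z1 <- splits$train                       # already standardized by pipeline
  st2 <- fit_standardizer(z1)
  z2 <- standardize(z1, st2)
  expect_equal(z2$windows, z1$windows, tolerance = 1e-6)
})

test_that("pipeline preserves window/label alignment", {
  # tag channel 2 with the label value so each window carries its own check
  L <- 640L
  labels <- rep(c(0L, 1L, 2L, 3L), each = 160L)
  sig <- rbind(rnorm(L), labels)
  rec <- raw_recording(sig, 25, labels = labels)
  b <- segment(rec, 16L, 8L)
  for (i in seq_len(mcae:::n_windows(b))) {
    tab <- table(as.integer(b$windows[i, 2, ]))
    expect_equal(as.integer(names(tab)[which.max(tab)]), b$labels[i])
  }
})
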