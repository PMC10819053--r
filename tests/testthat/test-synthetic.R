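test_that("recordings are reproducible and labeled per sample", {
  spec <- tiny_spec()
  r1 <- generate_recording(spec, 1, seed = 42)
  r2 <- generate_recording(spec, 1, seed = 42)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$labels, r2$labels)
  expect_false(identical(r1$signal, generate_recording(spec, 2, seed = 42)$signal))
  expect_equal(sort(unique(r1$labels)), 0:1)
  expect_equal(length(r1$labels), ncol(r1$signal))
})

test_that("subjects do not perturb each other's seed streams", {
  spec <- tiny_spec()
  alone <- generate_recording(spec, 3, seed = 5)
  invisible(generate_recording(spec, 1, seed = 5))   # consume RNG elsewhere
  again <- generate_recording(spec, 3, seed = 5)
  expect_identical(alone$signal, again$signal)
})

test_that("static segments match the stated noise model moments", {
  spec <- synthetic_spec(
    archetypes = list(
      class_archetype("still", "static", offset = 2),
      class_archetype("move", "periodic", base_freq = 1.5, amplitude = 1)),
    n_channels = 1L, sample_rate = 50, bout_seconds = c(20, 20),
    bouts_per_class = 2L, sigma_amp = 0, sigma_freq = 0, noise_sd = 0.1)
  rec <- generate_recording(spec, 1, seed = 3)
  x <- rec$signal[1, rec$labels == 0L]
  n <- length(x)
  expect_gt(n, 1500)
  se_mean <- 0.1 / sqrt(n)
  expect_lt(abs(mean(x) - 2), 3 * se_mean)
  se_sd <- 0.1 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(x) - 0.1), 3 * se_sd)
})

test_that("periodic segments peak at the configured frequency", {
  spec <- synthetic_spec(
    archetypes = list(
      class_archetype("move", "periodic", base_freq = 1.5, amplitude = 1,
                      harmonics = c(0.3, 0.1)),
      class_archetype("still", "static", offset = 0)),
    n_channels = 1L, sample_rate = 50, bout_seconds = c(20, 20),
    bouts_per_class = 1L, sigma_amp = 0, sigma_freq = 0, noise_sd = 0.05)
  rec <- generate_recording(spec, 1, seed = 8)
  # one contiguous periodic bout
  idx <- which(rec$labels == 0L)
  x <- rec$signal[1, idx]
  x <- x - mean(x)
  n <- length(x)
  freqs <- (seq_len(n) - 1) * spec$sample_rate / n
  mag <- Mod(stats::fft(x))[2:(n %/% 2)]
  peak <- freqs[1 + which.max(mag)]
  expect_lt(abs(peak - 1.5), 1 / (n / spec$sample_rate) + 1e-9)
})

test_that("Nyquist violations are rejected", {
  expect_error(synthetic_spec(
    archetypes = list(
      class_archetype("fast", "periodic", base_freq = 30, amplitude = 1),
      class_archetype("still", "static")),
    n_channels = 1L, sample_rate = 50), "Nyquist")
  # subject frequency offset pushing past Nyquist errors at generation
  spec <- synthetic_spec(
    archetypes = list(
      class_archetype("fast", "periodic", base_freq = 24.99, amplitude = 1),
      class_archetype("still", "static")),
    n_channels = 1L, sample_rate = 50, sigma_freq = 3, noise_sd = 0.1)
  msgs <- vapply(1:20, function(i)
    tryCatch({ generate_recording(spec, i, seed = 1); "" },
             error = function(e) conditionMessage(e)), "")
  expect_true(any(grepl("Nyquist", msgs)))
})

test_that("dataset splits are subject-disjoint with ~30% test subjects", {
  splits <- tiny_splits(n_subjects = 10, seed = 2)
  expect_equal(length(splits$subjects$test), 3L)    # round(0.3 * 10)
  all_ids <- c(splits$subjects$train, splits$subjects$val, splits$subjects$test)
  expect_equal(sort(all_ids), 1:10)                 # disjoint and complete
  tr <- unique(splits$train$subject_ids)
  te <- unique(splits$test$subject_ids)
  va <- unique(splits$val$subject_ids)
  expect_length(intersect(tr, te), 0)
  expect_length(intersect(tr, va), 0)
  expect_length(intersect(va, te), 0)
  expect_error(generate_dataset(tiny_spec(), n_subjects = 2), "3 subjects")
})

test_that("dataset generation is reproducible for a fixed seed", {
  s1 <- tiny_splits(seed = 4)
  s2 <- tiny_splits(seed = 4)
  expect_identical(s1$train$windows, s2$train$windows)
  expect_identical(s1$test$labels, s2$test$labels)
  expect_identical(s1$subjects, s2$subjects)
})

test_that("default benchmark spec yields a trainable population", {
  spec <- default_benchmark_spec()
  expect_equal(length(spec$archetypes), 4L)
  expect_equal(spec$n_channels, 6L)
  expect_equal(spec$sample_rate, 50)
  f <- vapply(Filter(function(a) a$kind == "periodic", spec$archetypes),
              function(a) a$base_freq[1], 1)
  expect_equal(sort(f), c(1.2, 2.0))
  offs <- lapply(Filter(function(a) a$kind == "static", spec$archetypes),
                 function(a) a$offset)
  expect_false(isTRUE(all.equal(offs[[1]], offs[[2]])))
  splits <- generate_dataset(spec, n_subjects = 8, seed = 1)
  expect_gte(mcae:::n_windows(splits$train), 500)
  expect_equal(sort(unique(splits$train$labels)), 0:3)
})
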