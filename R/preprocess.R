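#' Filtering configuration for raw recordings
#'
#' Defaults follow the noise-filtering stage commonly used for waist-worn
#' smartphone IMU data: a short running-median filter to suppress isolated
#' spikes followed by a zero-phase (forward-backward) low-pass Butterworth
#' filter. Human movement energy sits below roughly 20 Hz, hence the default
#' cutoff.
#'
#' @param median_kernel odd positive integer, width in samples of the running
#'   median filter.
#' @param butter_order order of the Butterworth low-pass.
#' @param butter_cutoff low-pass cutoff in Hz.
#' @param enabled logical; `FALSE` turns [denoise()] into a no-op.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(median_kernel = 3L, butter_order = 3L,
                          butter_cutoff = 20, enabled = TRUE) {
  median_kernel <- as.integer(median_kernel)
  butter_order <- as.integer(butter_order)
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("`median_kernel` must be an odd positive integer")
  if (butter_order < 1L) stop("`butter_order` must be a positive integer")
  if (!is.numeric(butter_cutoff) || butter_cutoff <= 0)
    stop("`butter_cutoff` must be > 0 (Hz)")
  structure(list(median_kernel = median_kernel, butter_order = butter_order,
                 butter_cutoff = as.numeric(butter_cutoff),
                 enabled = isTRUE(enabled)),
            class = "filter_config")
}

#' Denoise a recording (running median + zero-phase low-pass)
#'
#' Each channel is passed through a running-median filter of width
#' `cfg$median_kernel` and then a zero-phase Butterworth low-pass
#' (`signal::filtfilt`, so the effective magnitude response is the squared
#' one-pass response and no phase distortion is introduced). If the requested
#' cutoff is at or above the Nyquist frequency the low-pass stage is skipped
#' with a warning. Labels, subject id and shape are untouched.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [filter_config()].
#' @return the filtered `raw_recording`.
#' @export
denoise <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "filter_config"))
  if (!cfg$enabled) return(rec)
  bad <- which(!is.finite(rec$signal), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite sample in channel %d ('%s') at index %d",
                 bad[1, 1], rec$channel_names[bad[1, 1]], bad[1, 2]))
  nyquist <- rec$sample_rate / 2
  do_lowpass <- cfg$butter_cutoff < nyquist
  if (!do_lowpass)
    warning(sprintf(paste0("low-pass skipped: cutoff %g Hz is not below the ",
                           "Nyquist frequency %g Hz"),
                    cfg$butter_cutoff, nyquist))
  if (do_lowpass)
    bf <- signal::butter(cfg$butter_order, cfg$butter_cutoff / nyquist,
                         type = "low")
  out <- rec$signal
  L <- ncol(out)
  npad <- min(L - 1L, 9L * (cfg$butter_order + 1L))
  for (c in seq_len(nrow(out))) {
    x <- out[c, ]
    if (diff(range(x)) == 0) next       # constant channels pass unchanged
    if (cfg$median_kernel > 1L && L >= cfg$median_kernel)
      x <- as.numeric(stats::runmed(x, cfg$median_kernel, endrule = "keep"))
    if (do_lowpass && L > 3 * (cfg$butter_order + 1L)) {
      # odd-reflection padding suppresses the zero-phase filter's edge
      # transients, then the padding is trimmed away
      head_pad <- 2 * x[1] - x[(npad + 1L):2]
      tail_pad <- 2 * x[L] - x[(L - 1L):(L - npad)]
      xf <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
      x <- xf[(npad + 1L):(npad + L)]
    }
    out[c, ] <- x
  }
  rec$signal <- out
  rec
}

#' Magnitude response of the denoising low-pass at a frequency
#'
#' Evaluates the designed digital Butterworth filter's amplitude response at
#' `freq` Hz for a single forward pass; the zero-phase forward-backward
#' application in [denoise()] attenuates by the square of this value.
#'
#' @param cfg a [filter_config()].
#' @param freq frequency in Hz.
#' @param sample_rate sampling rate in Hz.
#' @return scalar amplitude gain in `[0, 1]`.
#' @export
lowpass_gain <- function(cfg, freq, sample_rate) {
  stopifnot(inherits(cfg, "filter_config"), freq >= 0,
            cfg$butter_cutoff < sample_rate / 2)
  bf <- signal::butter(cfg$butter_order, cfg$butter_cutoff / (sample_rate / 2),
                       type = "low")
  w <- 2 * pi * freq / sample_rate
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  Mod(sum(bf$b * z) / sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1))))
}

#' Window length in samples from a duration
#'
#' Converts a window duration in seconds to a sample count compatible with the
#' network's total temporal down-sampling factor of 16 (four pooling stages of
#' factor 2): `floor(seconds * sample_rate)` rounded down to the nearest
#' multiple of 16.
#'
#' @param seconds window duration in seconds.
#' @param sample_rate sampling frequency in Hz.
#' @return integer window length in samples (a multiple of 16).
#' @examples
#' window_samples(2.56, 50) # 128
#' window_samples(5, 100)   # 496
#' @export
window_samples <- function(seconds, sample_rate) {
  stopifnot(seconds > 0, sample_rate > 0)
  n <- floor(seconds * sample_rate + 1e-9)
  n <- as.integer(n - n %% 16L)
  if (n < 16L)
    stop("window shorter than 16 samples; increase `seconds` or `sample_rate`")
  n
}

#' Segment a recording into labeled windows
#'
#' Windows start at offsets `0, stride, 2*stride, ...` (half-open intervals),
#' giving `floor((L - T) / stride) + 1` candidate windows. Each window is
#' labeled by the majority of its per-sample labels; windows whose majority is
#' tied or whose majority label is `-1` (unlabeled) are dropped.
#'
#' @param rec a [raw_recording()].
#' @param window_length window length T in samples; must be a multiple of 16.
#' @param stride hop between window starts, in samples.
#' @return a [window_batch()] (or `NULL` if every window was dropped).
#' @export
segment <- function(rec, window_length, stride) {
  stopifnot(inherits(rec, "raw_recording"))
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  L <- ncol(rec$signal); C <- nrow(rec$signal)
  if (window_length %% 16L != 0L)
    stop("`window_length` must be divisible by 16; use window_samples() to pick one")
  if (window_length > L) stop("`window_length` exceeds the recording length")
  if (stride < 1L) stop("`stride` must be >= 1")
  starts <- seq.int(0L, L - window_length, by = stride)
  keep_label <- integer(0); keep_start <- integer(0)
  for (s in starts) {
    lab <- rec$labels[(s + 1L):(s + window_length)]
    tab <- table(lab)
    top <- max(tab)
    winners <- as.integer(names(tab)[tab == top])
    if (length(winners) != 1L || winners < 0L) next  # tie or unlabeled majority
    keep_label <- c(keep_label, winners)
    keep_start <- c(keep_start, s)
  }
  if (length(keep_start) == 0L) return(NULL)
  N <- length(keep_start)
  w <- array(0, c(N, C, window_length))
  for (i in seq_len(N))
    w[i, , ] <- rec$signal[, (keep_start[i] + 1L):(keep_start[i] + window_length)]
  window_batch(w, keep_label, rep(rec$subject_id, N), stride, rec$channel_names)
}

#' Combine window batches
#'
#' @param ... `window_batch` objects (NULLs are dropped) with identical
#'   channel count and window length.
#' @return a single [window_batch()].
#' @export
combine_batches <- function(...) {
  bs <- Filter(Negate(is.null), list(...))
  if (length(bs) == 0L) stop("no non-empty batches to combine")
  if (length(bs) == 1L) return(bs[[1]])
  d1 <- dim(bs[[1]]$windows)
  for (b in bs[-1]) {
    d <- dim(b$windows)
    if (d[2] != d1[2] || d[3] != d1[3])
      stop("all batches must share channel count and window length")
  }
  N <- sum(vapply(bs, n_windows, 1L))
  w <- array(0, c(N, d1[2], d1[3]))
  labels <- integer(N); subj <- vector(mode(bs[[1]]$subject_ids), N)
  at <- 0L
  for (b in bs) {
    n <- n_windows(b)
    w[(at + 1L):(at + n), , ] <- b$windows
    labels[(at + 1L):(at + n)] <- b$labels
    subj[(at + 1L):(at + n)] <- b$subject_ids
    at <- at + n
  }
  window_batch(w, labels, subj, bs[[1]]$stride, bs[[1]]$channel_names)
}

#' Fit per-channel standardization statistics
#'
#' Per-channel mean and standard deviation pooled over all windows and
#' timesteps of the training batch. The statistics are fitted on training data
#' only and then frozen, so validation and test windows are transformed with
#' the training-set moments.
#'
#' @param train a [window_batch()] of training windows.
#' @return an object of class `standardizer_stats` with `mean`, `std` (length
#'   C) and `fitted_on` (number of training windows).
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "window_batch"))
  d <- dim(train$windows)
  m <- numeric(d[2]); s <- numeric(d[2])
  for (c in seq_len(d[2])) {
    v <- as.numeric(train$windows[, c, ])
    m[c] <- mean(v)
    s[c] <- sqrt(mean((v - m[c])^2))  # population sd over all pooled samples
  }
  structure(list(mean = m, std = s, fitted_on = d[1],
                 channel_names = train$channel_names),
            class = "standardizer_stats")
}

#' Standardize a window batch with frozen statistics
#'
#' Transforms each channel as `(x - mean) / max(std, 1e-8)`; channels that
#' were constant in the training data therefore map to zero.
#'
#' @param batch a [window_batch()].
#' @param stats a `standardizer_stats` object from [fit_standardizer()].
#' @return the standardized `window_batch`.
#' @export
standardize <- function(batch, stats) {
  stopifnot(inherits(batch, "window_batch"), inherits(stats, "standardizer_stats"))
  C <- dim(batch$windows)[2]
  if (C != length(stats$mean))
    stop(sprintf("channel mismatch: batch has %d channels, stats were fitted on %d",
                 C, length(stats$mean)))
  for (c in seq_len(C))
    batch$windows[, c, ] <- (batch$windows[, c, ] - stats$mean[c]) /
      max(stats$std[c], 1e-8)
  batch
}
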