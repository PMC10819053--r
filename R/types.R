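#' Construct a raw multi-channel recording
#'
#' A `raw_recording` holds one subject's continuous multi-channel signal
#' (channels in rows, samples in columns) together with per-sample integer
#' activity labels (`-1` marks unlabeled samples) and a subject identifier.
#' It is the input unit of the preprocessing pipeline.
#'
#' @param signal numeric matrix, C channels x L samples.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param labels integer vector of length L; `-1` = unlabeled. Defaults to all
#'   unlabeled.
#' @param subject_id opaque subject identifier (scalar).
#' @param channel_names character vector of length C.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sample_rate, labels = NULL, subject_id = "s1",
                          channel_names = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)")
  C <- nrow(signal); L <- ncol(signal)
  if (L < 1L || C < 1L) stop("signal must have at least one channel and one sample")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar (Hz)")
  if (is.null(labels)) labels <- rep(-1L, L)
  labels <- as.integer(labels)
  if (length(labels) != L)
    stop(sprintf("`labels` must have length %d (one per sample), got %d", L, length(labels)))
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(rownames(signal))) rownames(signal)
                     else paste0("ch", seq_len(C))
  }
  if (length(channel_names) != C)
    stop("`channel_names` length must equal the number of channels")
  dimnames(signal) <- NULL
  structure(list(signal = signal, sample_rate = as.numeric(sample_rate),
                 labels = labels, subject_id = subject_id,
                 channel_names = as.character(channel_names)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject=%s  %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              as.character(x$subject_id), nrow(x$signal), ncol(x$signal),
              x$sample_rate, ncol(x$signal) / x$sample_rate))
  lab <- x$labels[x$labels >= 0L]
  if (length(lab)) {
    tab <- table(lab)
    cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  } else cat("  labels: none\n")
  invisible(x)
}

#' Construct a batch of segmented windows
#'
#' The universal tensor unit of the package: `N` windows of `C` channels and
#' `T` timesteps each, with one activity label and one subject id per window.
#'
#' @param windows numeric array N x C x T.
#' @param labels integer vector of length N, all >= 0.
#' @param subject_ids vector of length N.
#' @param stride window stride in samples.
#' @param channel_names character vector of length C.
#' @return an object of class `window_batch`.
#' @export
window_batch <- function(windows, labels, subject_ids, stride,
                         channel_names = NULL) {
  if (!is.array(windows) || length(dim(windows)) != 3L)
    stop("`windows` must be a 3-d array N x C x T")
  d <- dim(windows)
  if (d[1] < 1L) stop("a window batch must contain at least one window")
  labels <- as.integer(labels)
  if (length(labels) != d[1] || any(labels < 0L))
    stop("`labels` must have one non-negative entry per window")
  if (length(subject_ids) != d[1])
    stop("`subject_ids` must have one entry per window")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2]))
  structure(list(windows = windows, labels = labels,
                 subject_ids = subject_ids,
                 window_length = d[3], stride = as.integer(stride),
                 channel_names = as.character(channel_names)),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_batch> %d windows x %d channels x %d timesteps (stride %d)\n",
              d[1], d[2], d[3], x$stride))
  cat(sprintf("  %d subject(s), %d class(es)\n",
              length(unique(x$subject_ids)), length(unique(x$labels))))
  invisible(x)
}

n_windows <- function(batch) dim(batch$windows)[1]

#' Subset a window batch by window index
#'
#' @param batch a [window_batch()].
#' @param idx integer indices of the windows to keep.
#' @return a `window_batch` with the selected windows.
#' @export
batch_subset <- function(batch, idx) {
  window_batch(batch$windows[idx, , , drop = FALSE], batch$labels[idx],
               batch$subject_ids[idx], batch$stride, batch$channel_names)
}
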