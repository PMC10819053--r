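#' Write a recording to delimited text
#'
#' One row per sample: the C channel columns, then `label` and `subject`.
#' Values are written with 17 significant digits so the signal round-trips
#' exactly through [read_recording()]. The sampling rate is stored in a
#' `# sample_rate:` header comment.
#'
#' @param rec a [raw_recording()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate: %.17g", rec$sample_rate), con)
  writeLines(paste(c(rec$channel_names, "label", "subject"), collapse = sep), con)
  C <- nrow(rec$signal)
  cols <- vector("list", C + 2L)
  for (c in seq_len(C)) cols[[c]] <- sprintf("%.17g", rec$signal[c, ])
  cols[[C + 1L]] <- as.character(rec$labels)
  cols[[C + 2L]] <- rep(as.character(rec$subject_id), ncol(rec$signal))
  writeLines(do.call(paste, c(cols, sep = sep)), con)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Reads the format written by [write_recording()]: an optional
#' `# sample_rate:` header comment, a header row, and one row per sample
#' with channel columns plus `label` and `subject` columns (a `time` or
#' `timestamp` column, if present, is ignored).
#'
#' @param path input file path.
#' @param sample_rate sampling rate in Hz; required when the file carries no
#'   `# sample_rate:` header.
#' @param sep field separator.
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, sample_rate = NULL, sep = ",") {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# sample_rate:")) {
    hdr_rate <- as.numeric(sub("# sample_rate:", "", first))
    if (is.null(sample_rate)) sample_rate <- hdr_rate
  }
  if (is.null(sample_rate))
    stop("`sample_rate` must be given when the file has no '# sample_rate:' header")
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  drop <- tolower(names(df)) %in% c("time", "timestamp")
  df <- df[, !drop, drop = FALSE]
  if (!all(c("label", "subject") %in% names(df)))
    stop("recording file needs 'label' and 'subject' columns")
  subj <- unique(df$subject)
  if (length(subj) != 1L)
    stop("a recording file must contain exactly one subject")
  ch <- setdiff(names(df), c("label", "subject"))
  raw_recording(t(as.matrix(df[, ch, drop = FALSE])), sample_rate,
                labels = df$label, subject_id = subj, channel_names = ch)
}

#' Read a pre-segmented fixed-width dataset directory (convenience adapter)
#'
#' Convenience adapter for directories laid out like the common smartphone
#' HAR benchmark distribution: per-channel fixed-width text files of
#' pre-segmented windows (one window per row) under
#' `<dir>/<split>/Inertial Signals/`, plus `y_<split>.txt` (1-based labels)
#' and `subject_<split>.txt`. This adapter is a convenience only and is not
#' validated against the original distribution.
#'
#' @param dir dataset root directory.
#' @param split `"train"` or `"test"`.
#' @param channels character vector of channel file stems (without
#'   `_<split>.txt`).
#' @return a [window_batch()] (labels shifted to 0-based).
#' @export
read_presegmented_dir <- function(dir, split = c("train", "test"),
                                  channels = NULL) {
  split <- match.arg(split)
  sig_dir <- file.path(dir, split, "Inertial Signals")
  if (!dir.exists(sig_dir)) stop("no 'Inertial Signals' directory under ", sig_dir)
  if (is.null(channels)) {
    fs <- list.files(sig_dir, pattern = paste0("_", split, "\\.txt$"))
    channels <- sub(paste0("_", split, "\\.txt$"), "", fs)
  }
  if (length(channels) == 0L) stop("no channel files found in ", sig_dir)
  mats <- lapply(channels, function(ch) {
    as.matrix(utils::read.table(file.path(sig_dir, paste0(ch, "_", split, ".txt"))))
  })
  N <- nrow(mats[[1]]); T <- ncol(mats[[1]])
  w <- array(0, c(N, length(channels), T))
  for (c in seq_along(mats)) w[, c, ] <- mats[[c]]
  labels <- utils::read.table(file.path(dir, split, paste0("y_", split, ".txt")))[, 1] - 1L
  subj <- utils::read.table(file.path(dir, split, paste0("subject_", split, ".txt")))[, 1]
  window_batch(w, labels, subj, stride = T %/% 2L, channel_names = channels)
}
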