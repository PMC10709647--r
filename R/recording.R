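#' Construct a continuous multichannel EEG recording
#'
#' The basic container moved through the pipeline: a channels x samples
#' matrix in microvolts with montage labels, sampling rate, group label and
#' eyes-closed interval annotations.
#'
#' @param subject_id character scalar.
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_labels character vector, one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param group_label one of `"ASD-like"`, `"TD-like"`, `"unknown"`.
#' @param eyes_closed list of numeric `c(start_s, end_s)` intervals; by
#'   default a single interval spanning the full recording.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(subject_id, data, channel_labels, fs,
                          group_label = "unknown",
                          eyes_closed = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (nrow(data) != length(channel_labels))
    stop("data has ", nrow(data), " rows but ", length(channel_labels),
         " channel labels were given")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  group_label <- match.arg(group_label, c("ASD-like", "TD-like", "unknown"))
  dur <- ncol(data) / fs
  if (is.null(eyes_closed)) eyes_closed <- list(c(0, dur))
  for (iv in eyes_closed) {
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > dur + 1e-9 || iv[2] <= iv[1])
      stop("invalid eyes-closed interval: [", iv[1], ", ", iv[2],
           "] for a recording of ", dur, " s")
  }
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id),
         group_label = group_label,
         channel_labels = as.character(channel_labels),
         fs = fs, data = data,
         eyes_closed = eyes_closed),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s), %d eyes-closed interval(s)\n",
              x$subject_id, x$group_label, nrow(x$data), ncol(x$data),
              x$fs, ncol(x$data) / x$fs, length(x$eyes_closed)))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$data) / rec$fs
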