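#' Re-reference a recording to the Fz electrode
#'
#' Every remaining channel becomes `original - Fz`; the reference channel is
#' removed, so the 19-channel montage yields 18 analysis channels. An
#' average reference is deliberately not offered: it mixes signal phases,
#' which corrupts phase-coupling measures.
#'
#' @param recording an `eeg_recording` containing the reference channel.
#' @param reference reference channel label (default `"Fz"`).
#' @return An `eeg_recording` without the reference channel.
#' @export
rereference_to_fz <- function(recording, reference = "Fz") {
  stopifnot(inherits(recording, "eeg_recording"))
  k <- match(reference, recording$channel_labels)
  if (is.na(k))
    stop("reference channel '", reference, "' not present; available: ",
         paste(recording$channel_labels, collapse = ", "))
  ref <- recording$data[k, ]
  out <- recording
  out$data <- sweep(recording$data[-k, , drop = FALSE], 2, ref)
  out$channel_labels <- recording$channel_labels[-k]
  rownames(out$data) <- out$channel_labels
  out
}

# sample index ranges of the whole eyes-closed intervals
eyes_closed_sample_ranges <- function(recording) {
  lapply(recording$eyes_closed, function(iv) {
    from <- floor(iv[1] * recording$fs) + 1L
    to <- min(floor(iv[2] * recording$fs), ncol(recording$data))
    c(from, to)
  })
}

#' Cut a recording into fixed-length eyes-closed epochs
#'
#' Non-overlapping consecutive epochs are tiled within each eyes-closed
#' interval; trailing partial segments are discarded so every epoch has the
#' same length (the `T` of the phase-locking formulas).
#'
#' @param recording an `eeg_recording`.
#' @param epoch_s epoch length in seconds (default 2).
#' @return An object of class `epoch_set`: list with `subject_id`,
#'   `group_label`, `channel_labels`, `fs`, and `epochs`, an array
#'   `n_epochs x channels x L`.
#' @export
extract_epochs <- function(recording, epoch_s = 2) {
  stopifnot(inherits(recording, "eeg_recording"), epoch_s > 0)
  L <- round(epoch_s * recording$fs)
  nch <- nrow(recording$data)
  pieces <- list()
  for (rg in eyes_closed_sample_ranges(recording)) {
    n_ep <- (rg[2] - rg[1] + 1L) %/% L
    if (n_ep < 1L) next
    for (e in seq_len(n_ep)) {
      from <- rg[1] + (e - 1L) * L
      pieces[[length(pieces) + 1L]] <-
        recording$data[, from:(from + L - 1L), drop = FALSE]
    }
  }
  if (!length(pieces))
    stop("no eyes-closed interval of at least ", epoch_s,
         " s in recording ", recording$subject_id)
  epochs <- array(0, dim = c(length(pieces), nch, L))
  for (e in seq_along(pieces)) epochs[e, , ] <- pieces[[e]]
  if (anyNA(epochs)) stop("NA values in epoched data")
  structure(
    list(subject_id = recording$subject_id,
         group_label = recording$group_label,
         channel_labels = recording$channel_labels,
         fs = recording$fs, epochs = epochs),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %s: %d epochs x %d ch x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Standard preprocessing of one recording
#'
#' Broadband 1-45 Hz zero-phase FIR filtering, re-referencing to Fz and
#' channel-label canonicalisation. Band-specific filtering and epoching
#' happen downstream (on the continuous signal, to keep 2-s segments free
#' of filter edge transients).
#'
#' @param recording an `eeg_recording` with the 19-channel montage.
#' @param f_low,f_high broadband passband edges, Hz.
#' @param reference reference electrode label.
#' @return A filtered, re-referenced `eeg_recording` (18 channels).
#' @export
preprocess_recording <- function(recording, f_low = 1, f_high = 45,
                                 reference = "Fz") {
  rec <- recording
  rec$channel_labels <- normalize_channel_labels(rec$channel_labels)
  rownames(rec$data) <- rec$channel_labels
  bb <- design_bandpass(f_low, f_high, rec$fs)
  rereference_to_fz(apply_filter(rec, bb), reference = reference)
}
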