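#' Write a recording to a European Data Format (EDF) file
#'
#' Minimal plain-EDF writer: one 1-second data record per elapsed second,
#' 16-bit samples, physical dimension microvolts, per-channel physical
#' scaling. Annotations are not embedded; eyes-closed intervals travel in
#' the cohort sidecar (see [write_cohort_edf()]). Trailing samples that do
#' not fill a whole record are dropped.
#'
#' @param recording an `eeg_recording` with an integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer fs")
  fs <- as.integer(round(fs))
  x <- recording$data
  ns <- nrow(x)
  n_rec <- ncol(x) %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1-s data record")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  pad <- function(s, w) {
    s <- substr(as.character(s), 1L, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  pmax_ch <- pmax(apply(abs(x), 1, max), 1e-6)
  phys_min <- -pmax_ch
  phys_max <- pmax_ch
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8L), pad(recording$subject_id, 80L),
    pad(paste("group:", recording$group_label), 80L),
    pad("01.01.00", 8L), pad("00.00.00", 8L),
    pad(256L * (1L + ns), 8L), pad("", 44L),
    pad(n_rec, 8L), pad("1", 8L), pad(ns, 4L)
  ), con, eos = NULL)
  fields <- list(
    list(recording$channel_labels, 16L), list(rep("", ns), 80L),
    list(rep("uV", ns), 8L),
    list(sprintf("%.6g", phys_min), 8L), list(sprintf("%.6g", phys_max), 8L),
    list(rep("-32768", ns), 8L), list(rep("32767", ns), 8L),
    list(rep("", ns), 80L), list(rep(fs, ns), 8L), list(rep("", ns), 32L))
  for (f in fields)
    writeChar(paste(vapply(f[[1]], pad, character(1), f[[2]]),
                    collapse = ""), con, eos = NULL)
  dig <- matrix(0L, ns, ncol(x))
  for (c_idx in seq_len(ns)) {
    dig[c_idx, ] <- as.integer(round(
      (x[c_idx, ] - phys_min[c_idx]) / (phys_max[c_idx] - phys_min[c_idx]) *
        65535 - 32768))
  }
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, sel, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses plain EDF with equal per-signal sampling rates. Channel labels
#' are canonicalised with [normalize_channel_labels()] when they match the
#' 10-20 set.
#'
#' @param path EDF file.
#' @param group_label optional group label to attach.
#' @param eyes_closed optional list of intervals (seconds).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, group_label = "unknown", eyes_closed = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L)                       # version
  subject_id <- rd(80L)
  rd(80L); rd(8L); rd(8L); rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  dur_rec <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  for (i in seq_len(ns)) rd(80L)      # transducer
  for (i in seq_len(ns)) rd(8L)       # dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  for (i in seq_len(ns)) rd(80L)      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / dur_rec
  x <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    for (c_idx in seq_len(ns)) {
      sel <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      x[c_idx, sel] <- phys_min[c_idx] +
        (block[, c_idx] - dig_min[c_idx]) /
          (dig_max[c_idx] - dig_min[c_idx]) *
          (phys_max[c_idx] - phys_min[c_idx])
    }
  }
  labels <- tryCatch(normalize_channel_labels(labels),
                     error = function(e) labels)
  new_recording(subject_id, x, labels, fs, group_label = group_label,
                eyes_closed = eyes_closed)
}

#' Write a cohort as EDF files plus sidecar tables
#'
#' One EDF per subject plus `cohort.csv` (subject_id, group_label, file)
#' and `intervals.csv` (subject_id, start_s, end_s) holding the
#' eyes-closed annotations.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param dir output directory (created if needed).
#' @return Path of the sidecar CSV, invisibly.
#' @export
write_cohort_edf <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- data.frame(subject_id = character(0), group_label = character(0),
                        file = character(0))
  ivs <- data.frame(subject_id = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  for (rec in recordings) {
    f <- paste0(rec$subject_id, ".edf")
    write_edf(rec, file.path(dir, f))
    sidecar <- rbind(sidecar, data.frame(subject_id = rec$subject_id,
                                         group_label = rec$group_label,
                                         file = f))
    for (iv in rec$eyes_closed)
      ivs <- rbind(ivs, data.frame(subject_id = rec$subject_id,
                                   start_s = iv[1], end_s = iv[2]))
  }
  utils::write.csv(sidecar, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(ivs, file.path(dir, "intervals.csv"), row.names = FALSE)
  invisible(file.path(dir, "cohort.csv"))
}

#' Read a cohort written by [write_cohort_edf()]
#'
#' @param dir directory containing `cohort.csv`, `intervals.csv` and the
#'   EDF files.
#' @return List of `eeg_recording` objects.
#' @export
read_cohort_edf <- function(dir) {
  sidecar <- utils::read.csv(file.path(dir, "cohort.csv"),
                             stringsAsFactors = FALSE)
  ivpath <- file.path(dir, "intervals.csv")
  ivs <- if (file.exists(ivpath))
    utils::read.csv(ivpath, stringsAsFactors = FALSE) else NULL
  out <- list()
  for (i in seq_len(nrow(sidecar))) {
    sid <- sidecar$subject_id[i]
    eyes <- NULL
    if (!is.null(ivs)) {
      sub <- ivs[ivs$subject_id == sid, , drop = FALSE]
      if (nrow(sub))
        eyes <- lapply(seq_len(nrow(sub)),
                       function(r) c(sub$start_s[r], sub$end_s[r]))
    }
    out[[sid]] <- read_edf(file.path(dir, sidecar$file[i]),
                           group_label = sidecar$group_label[i],
                           eyes_closed = eyes)
  }
  out
}
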