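#' Welch power spectral density of one epoch
#'
#' Hamming-windowed Welch estimate with 1-s segments and 50% overlap
#' (1 Hz resolution inside a 2-s epoch, three averaged windows at 250 Hz).
#' One-sided density scaling: `sum(psd) * df` approximates the signal
#' variance.
#'
#' @param epoch numeric matrix channels x L, or a vector for one channel.
#' @param fs sampling rate, Hz.
#' @param nperseg window length in samples (default `fs`, i.e. 1 s).
#' @param overlap fractional window overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (channels x frequencies,
#'   microvolts^2/Hz).
#' @export
welch_psd <- function(epoch, fs, nperseg = round(fs), overlap = 0.5) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1L)
  L <- ncol(epoch)
  nperseg <- as.integer(nperseg)
  if (L < nperseg)
    stop("epoch (", L, " samples) shorter than one Welch window (",
         nperseg, ")")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, L - nperseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1L) / (nperseg - 1L))
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2L + 1L
  acc <- matrix(0, nrow(epoch), nf)
  for (s0 in starts) {
    seg <- epoch[, s0:(s0 + nperseg - 1L), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))           # detrend: constant
    seg <- sweep(seg, 2, w, `*`)
    sp <- stats::mvfft(t(seg))[seq_len(nf), , drop = FALSE]
    p <- (Mod(sp)^2) * scale
    # one-sided: double everything except DC (and Nyquist when present)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nperseg %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + t(p * dbl)
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg,
       psd = acc / length(starts))
}

#' Average band power from a PSD
#'
#' Mean of the PSD over grid frequencies `f_low <= f <= f_high`, inclusive
#' at both edges.
#'
#' @param psd list as returned by [welch_psd()].
#' @param band one row of [eeg_bands()] (or any list with `f_low`,
#'   `f_high`).
#' @return Numeric vector, one power per channel.
#' @export
band_power <- function(psd, band) {
  sel <- psd$freq >= band$f_low - 1e-9 & psd$freq <= band$f_high + 1e-9
  if (!any(sel))
    stop("band ", band$f_low, "-", band$f_high,
         " Hz does not intersect the PSD grid")
  rowMeans(psd$psd[, sel, drop = FALSE])
}

#' Min-max rescale band powers across electrodes
#'
#' Per 2-s segment and band, the minimum across channels maps to 0 and the
#' maximum to 1; a degenerate all-equal input maps to all 0.5.
#'
#' @param x numeric vector (one value per channel).
#' @return Rescaled vector in \[0, 1\].
#' @export
normalize_segment <- function(x) {
  if (!all(is.finite(x))) stop("non-finite band powers")
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Spectral feature matrix of one subject
#'
#' Per epoch: Welch PSD per channel, band power per canonical band,
#' min-max rescaling across the 18 electrodes within each band; the
#' rescaled values are then averaged across epochs. With 18 channels the
#' flattened vector has the canonical width 72.
#'
#' @param epochs an `epoch_set` (post-reference, broadband-filtered).
#' @return An object of class `spectral_features`: list with `subject_id`,
#'   `group_label`, `matrix` (channels x 4 bands, entries in \[0, 1\]) and
#'   `n_epochs_used`.
#' @export
subject_spectral_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  if (d[1] < 1L) stop("no epochs")
  bands <- eeg_bands()
  acc <- matrix(0, d[2], nrow(bands),
                dimnames = list(epochs$channel_labels, bands$name))
  for (e in seq_len(d[1])) {
    psd <- welch_psd(epochs$epochs[e, , ], epochs$fs)
    for (b in seq_len(nrow(bands))) {
      acc[, b] <- acc[, b] + normalize_segment(band_power(psd, bands[b, ]))
    }
  }
  structure(
    list(subject_id = epochs$subject_id, group_label = epochs$group_label,
         matrix = acc / d[1], n_epochs_used = d[1]),
    class = "spectral_features")
}

#' Cohort spectral feature table
#'
#' Runs [preprocess_recording()], [extract_epochs()] and
#' [subject_spectral_features()] over a list of recordings and assembles
#' the subjects x 72 feature table with `<channel>_<band>` column names.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param epoch_s epoch length, seconds.
#' @return An object of class `feature_table`: list with `x` (matrix
#'   subjects x features), `feature_names`, `subject_ids`, `labels`
#'   (group labels) and `set = "spectral"`.
#' @export
spectral_feature_table <- function(recordings, epoch_s = 2) {
  rows <- lapply(recordings, function(rec) {
    if ("Fz" %in% rec$channel_labels) rec <- preprocess_recording(rec)
    sf <- subject_spectral_features(extract_epochs(rec, epoch_s = epoch_s))
    list(v = as.vector(sf$matrix),
         names = as.vector(outer(rownames(sf$matrix), colnames(sf$matrix),
                                 paste, sep = "_")),
         id = sf$subject_id, grp = sf$group_label)
  })
  x <- do.call(rbind, lapply(rows, `[[`, "v"))
  colnames(x) <- rows[[1]]$names
  rownames(x) <- vapply(rows, `[[`, character(1), "id")
  new_feature_table(x, vapply(rows, `[[`, character(1), "grp"), "spectral")
}

new_feature_table <- function(x, labels, set) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  structure(
    list(x = x, feature_names = colnames(x), subject_ids = rownames(x),
         labels = labels, set = set),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d subjects x %d features (%s)\n",
              x$set, nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}
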