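#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: negative frequencies zeroed, positive doubled.
#'
#' @param x numeric matrix channels x samples (or a vector).
#' @return Complex matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  h <- rep(0, n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  t(stats::mvfft(stats::mvfft(t(x)) * h, inverse = TRUE)) / n
}

#' Instantaneous phase of band-limited signals
#'
#' The complex argument of the analytic signal, per channel and sample.
#' Meaningful only for band-limited input; feed it the output of a
#' band-pass [apply_filter()] step.
#'
#' @param x numeric matrix channels x samples (band-filtered), or vector.
#' @return Matrix of phases in (-pi, pi], same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (any(apply(abs(x), 1, max) == 0))
    stop("all-zero channel: instantaneous phase undefined")
  Arg(analytic_signal(x))
}

#' Phase-locking value of two phase sequences
#'
#' `PLV = (1/T) |sum_t exp(-i (phi_i(t) - phi_j(t)))|`, in \[0, 1\];
#' 1 means a perfectly constant phase difference, ~0 independence.
#'
#' @param phases_i,phases_j numeric vectors of equal length `T >= 2`
#'   (radians).
#' @return Scalar in \[0, 1\].
#' @export
plv <- function(phases_i, phases_j) {
  if (length(phases_i) != length(phases_j))
    stop("phase sequences differ in length")
  if (length(phases_i) < 2L) stop("need T >= 2 samples")
  Mod(mean(exp(-1i * (phases_i - phases_j))))
}

#' Corrected imaginary phase-locking value
#'
#' `|Im(mean phasor)| / sqrt(1 - Re(mean phasor)^2)`: keeps only non-zero
#' lag coupling, so instantaneous (volume-conducted) zero-lag locking is
#' suppressed. Magnitude convention: values in \[0, 1\]. When the mean
#' phasor is almost exactly real (near-perfect zero-lag locking) the
#' denominator vanishes together with the numerator; 0 is returned with a
#' warning.
#'
#' @inheritParams plv
#' @param eps denominator guard (default 1e-9).
#' @return Scalar in \[0, 1\].
#' @export
ciplv <- function(phases_i, phases_j, eps = 1e-9) {
  if (length(phases_i) != length(phases_j))
    stop("phase sequences differ in length")
  if (length(phases_i) < 2L) stop("need T >= 2 samples")
  m <- mean(exp(-1i * (phases_i - phases_j)))
  den2 <- 1 - Re(m)^2
  if (den2 < eps^2) {
    warning("near-perfect zero-lag locking: ciPLV denominator ~ 0, returning 0")
    return(0)
  }
  abs(Im(m)) / sqrt(den2)
}

# band-filter a (preprocessed) recording, Hilbert on each continuous
# eyes-closed stretch, then epoch the phases; returns band -> epoch_set of
# phases (Hilbert runs before epoching to avoid per-epoch edge bias)
band_phase_epochs <- function(recording, epoch_s = 2) {
  bands <- eeg_bands()
  out <- list()
  for (b in seq_len(nrow(bands))) {
    spec <- design_bandpass(bands$f_low[b], bands$f_high[b], recording$fs,
                            order = bands$order[b])
    filt <- apply_filter(recording, spec)
    ph <- filt
    for (rg in eyes_closed_sample_ranges(filt)) {
      seg <- filt$data[, rg[1]:rg[2], drop = FALSE]
      ph$data[, rg[1]:rg[2]] <- instantaneous_phase(seg)
    }
    out[[bands$name[b]]] <- extract_epochs(ph, epoch_s = epoch_s)
  }
  out
}

# mean phasor matrix over one phase epoch (channels x L):
# M[i, j] = (1/L) sum_t exp(-i (phi_i - phi_j))
epoch_mean_phasors <- function(phi) {
  E <- exp(-1i * phi)
  (E %*% Conj(t(E))) / ncol(phi)
}

#' Per-subject connectivity features
#'
#' PLV or ciPLV for every unique channel pair in each canonical band,
#' evaluated on 2-s phase epochs and averaged across epochs. With 18
#' post-reference channels: 153 pairs x 4 bands = 612 features.
#'
#' @param phase_epochs per-band phase epochs from the internal pipeline,
#'   or an `eeg_recording` (already preprocessed / 18 channels), in which
#'   case band filtering, Hilbert transform and epoching are run here.
#' @param measure `"plv"` or `"ciplv"`.
#' @param epoch_s epoch length, seconds (used when a recording is given).
#' @return An object of class `connectivity_features`: list with
#'   `subject_id`, `group_label`, `measure`, `pairs` (the fixed pair
#'   order), `matrix` (pairs x bands) and `n_epochs_used`.
#' @export
subject_connectivity <- function(phase_epochs, measure = c("plv", "ciplv"),
                                 epoch_s = 2) {
  measure <- match.arg(measure)
  if (inherits(phase_epochs, "eeg_recording"))
    phase_epochs <- band_phase_epochs(phase_epochs, epoch_s = epoch_s)
  bands <- names(phase_epochs)
  es1 <- phase_epochs[[1]]
  labels <- es1$channel_labels
  prs <- channel_pairs(labels)
  ui <- cbind(prs$i, prs$j)
  vals <- matrix(0, nrow(prs), length(bands),
                 dimnames = list(paste(prs$a, prs$b, sep = "-"), bands))
  for (b in seq_along(bands)) {
    es <- phase_epochs[[b]]
    n_ep <- dim(es$epochs)[1]
    if (n_ep < 1L) stop("no epochs for band ", bands[b])
    acc <- numeric(nrow(prs))
    for (e in seq_len(n_ep)) {
      M <- epoch_mean_phasors(es$epochs[e, , ])
      m <- M[ui]
      if (measure == "plv") {
        acc <- acc + Mod(m)
      } else {
        den2 <- 1 - Re(m)^2
        v <- ifelse(den2 < 1e-18, 0, abs(Im(m)) / sqrt(pmax(den2, 1e-18)))
        if (any(den2 < 1e-18))
          warning("near-perfect zero-lag locking in band ", bands[b],
                  ": ciPLV set to 0 for the affected pair(s)")
        acc <- acc + v
      }
    }
    vals[, b] <- acc / n_ep
  }
  structure(
    list(subject_id = es1$subject_id, group_label = es1$group_label,
         measure = measure, pairs = prs, matrix = vals,
         n_epochs_used = dim(es1$epochs)[1]),
    class = "connectivity_features")
}

#' Cohort connectivity feature table
#'
#' Preprocesses each recording (unless already reduced to 18 channels),
#' computes per-subject PLV or ciPLV features and assembles the
#' subjects x 612 table with `<chanA>-<chanB>_<band>_<measure>` columns
#' (band-major, pairs in the fixed lexicographic order).
#'
#' @param recordings list of `eeg_recording` objects.
#' @param measure `"plv"` or `"ciplv"`.
#' @param epoch_s epoch length, seconds.
#' @return A `feature_table` (see [spectral_feature_table()]).
#' @export
connectivity_feature_table <- function(recordings, measure = c("plv", "ciplv"),
                                       epoch_s = 2) {
  measure <- match.arg(measure)
  rows <- lapply(recordings, function(rec) {
    if ("Fz" %in% rec$channel_labels) rec <- preprocess_recording(rec)
    cf <- subject_connectivity(rec, measure = measure, epoch_s = epoch_s)
    nm <- as.vector(outer(rownames(cf$matrix), colnames(cf$matrix),
                          function(p, b) paste0(p, "_", b, "_", measure)))
    list(v = as.vector(cf$matrix), names = nm,
         id = cf$subject_id, grp = cf$group_label)
  })
  x <- do.call(rbind, lapply(rows, `[[`, "v"))
  colnames(x) <- rows[[1]]$names
  rownames(x) <- vapply(rows, `[[`, character(1), "id")
  new_feature_table(x, vapply(rows, `[[`, character(1), "grp"), measure)
}

#' Square connectivity matrices of one subject
#'
#' Expands the pair vector of a `connectivity_features` object into a
#' symmetric 18 x 18 matrix per band (diagonal zero), convenient for
#' plotting or export.
#'
#' @param cf a `connectivity_features` object.
#' @return Named list of symmetric matrices, one per band.
#' @export
connectivity_matrices <- function(cf) {
  stopifnot(inherits(cf, "connectivity_features"))
  labels <- unique(c(cf$pairs$a, cf$pairs$b))
  n <- length(labels)
  lapply(stats::setNames(colnames(cf$matrix), colnames(cf$matrix)),
         function(b) {
           m <- matrix(0, n, n, dimnames = list(labels, labels))
           m[cbind(cf$pairs$i, cf$pairs$j)] <- cf$matrix[, b]
           m + t(m)
         })
}
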