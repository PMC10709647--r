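#' Design a Hamming-window FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase type-I design. When `order` is not
#' given it is estimated from the heuristic transition bandwidth: 25% of the
#' lower passband edge, floored at 2 Hz, and limited by the distance to the
#' critical frequencies (DC, Nyquist). The -6 dB cutoffs are placed half a
#' transition band outside the passband edges, and the coefficients are
#' scaled to unit gain at the passband centre.
#'
#' @param f_low,f_high passband edges in Hz, `0 < f_low < f_high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order optional even filter order (taps - 1); e.g. 24 for the
#'   theta/alpha/low-beta connectivity filters and 50 for high beta.
#' @return An object of class `fir_spec` with elements `h` (coefficients),
#'   `order`, `f_low`, `f_high`, `fc_low`, `fc_high`, `transition_bw`,
#'   `fs`, `window = "hamming"`, `zero_phase = TRUE`.
#' @seealso [apply_filter()], [fir_response()]
#' @export
design_bandpass <- function(f_low, f_high, fs, order = NULL) {
  if (!(f_low > 0 && f_high > f_low)) stop("need 0 < f_low < f_high")
  if (f_high >= fs / 2)
    stop("f_high (", f_high, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  tb <- max(0.25 * f_low, 2)
  # per-edge limit: the transition band may not cross DC or Nyquist
  tb_low <- min(tb, f_low)
  tb_high <- min(tb, fs / 2 - f_high)
  if (is.null(order)) {
    order <- ceiling(3.3 * fs / min(tb_low, tb_high))
    if (order %% 2L == 1L) order <- order + 1L
  } else {
    order <- as.integer(order)
    if (order < 2L || order %% 2L != 0L)
      stop("order must be an even integer >= 2 (linear-phase type I)")
  }
  # -6 dB cutoffs half a transition band outside the passband edges
  fc_low <- f_low - tb_low / 2
  fc_high <- f_high + tb_high / 2
  m <- seq_len(order + 1L) - 1L - order / 2
  h <- ifelse(m == 0,
              2 * (fc_high - fc_low) / fs,
              (sin(2 * pi * fc_high * m / fs) - sin(2 * pi * fc_low * m / fs)) /
                (pi * m))
  n <- seq(0, order)
  h <- h * (0.54 - 0.46 * cos(2 * pi * n / order))
  centre <- (f_low + f_high) / 2
  g <- Mod(sum(h * exp(-2i * pi * centre * m / fs)))
  h <- h / g
  structure(
    list(h = h, order = order, f_low = f_low, f_high = f_high,
         fc_low = fc_low, fc_high = fc_high, transition_bw = tb,
         fs = fs, window = "hamming", zero_phase = TRUE),
    class = "fir_spec")
}

#' @export
print.fir_spec <- function(x, ...) {
  cat(sprintf("<fir_spec> Hamming FIR band-pass %g-%g Hz @ %g Hz, order %d (%d taps), zero-phase\n",
              x$f_low, x$f_high, x$fs, x$order, x$order + 1L))
  invisible(x)
}

#' Amplitude response of an FIR design
#'
#' The design is symmetric (type I), so the response at each frequency is a
#' real amplitude (zero phase once delay-compensated).
#'
#' @param spec a `fir_spec`.
#' @param freqs frequencies in Hz.
#' @return Numeric vector of amplitude gains (can carry stopband-ripple
#'   sign), same length as `freqs`.
#' @export
fir_response <- function(spec, freqs) {
  m <- seq(0, spec$order) - spec$order / 2
  vapply(freqs,
         function(f) sum(spec$h * cos(2 * pi * f * m / spec$fs)),
         numeric(1))
}

# Zero-phase FIR filtering of a samples x channels matrix.
# Symmetric (linear-phase) taps applied centred: the group delay of
# (order/2) samples is compensated exactly, so the output has zero phase
# distortion at every frequency. Edges are odd-reflection padded.
fir_filter_columns <- function(x, h) {
  nh <- length(h)
  n <- nrow(x)
  npad <- nh
  if (npad + 1L > n) stop("signal too short for this filter")
  top <- 2 * x[rep(1L, npad), , drop = FALSE] - x[(npad + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(n, npad), , drop = FALSE] - x[(n - 1L):(n - npad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np + nh - 1L, 2)
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  delay <- (nh - 1L) / 2
  y[(npad + delay + 1L):(npad + delay + n), , drop = FALSE]
}

#' Apply an FIR filter to a recording, zero-phase
#'
#' Per-channel convolution with delay compensation (the symmetric taps are
#' applied centred), so no frequency-dependent phase shift enters the
#' instantaneous-phase estimates downstream. Signal length is preserved;
#' edges are handled by odd reflection padding. Channel means are removed
#' first: DC lies outside every passband used here and an exact DC null is
#' not achievable with a windowed-sinc stopband alone.
#'
#' @param recording an `eeg_recording`.
#' @param spec a `fir_spec` designed at the recording's sampling rate.
#' @return A filtered `eeg_recording`.
#' @export
apply_filter <- function(recording, spec) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(spec, "fir_spec"))
  if (abs(recording$fs - spec$fs) > 1e-9)
    stop("filter designed at ", spec$fs, " Hz but recording sampled at ",
         recording$fs, " Hz")
  nh <- spec$order + 1L
  if (ncol(recording$data) < 3L * nh)
    stop("signal (", ncol(recording$data), " samples) shorter than 3 x filter length (",
         3L * nh, "); edge handling would dominate")
  x <- t(recording$data)
  x <- sweep(x, 2, colMeans(x))
  y <- t(fir_filter_columns(x, spec$h))
  out <- recording
  out$data <- y
  rownames(out$data) <- out$channel_labels
  out
}
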