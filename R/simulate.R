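#' Specify a phase coupling between two channels
#'
#' A coupled pair shares one band-limited oscillator; the second channel
#' lags the first by `lag_rad` plus a smooth, zero-mean von Mises jitter of
#' concentration `kappa`. The expected phase-locking value of the pair is
#' the von Mises mean resultant length I1(kappa)/I0(kappa).
#'
#' @param pair character vector of two distinct channel labels.
#' @param band band name (`"theta"`, `"alpha"`, `"beta1"`, `"beta2"`).
#' @param lag_rad phase lag in radians, in (-pi, pi].
#' @param kappa von Mises concentration, >= 0 (`Inf` = no jitter).
#' @param group `"both"` (default), `"ASD-like"` or `"TD-like"`.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(pair, band, lag_rad, kappa, group = "both") {
  stopifnot(length(pair) == 2L, is.character(pair))
  if (pair[1] == pair[2]) stop("coupling pair members must be distinct")
  band <- match.arg(band, eeg_bands()$name)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop("kappa must be a single number >= 0")
  if (!(lag_rad > -pi && lag_rad <= pi + 1e-12))
    stop("lag_rad must lie in (-pi, pi]")
  group <- match.arg(group, c("both", "ASD-like", "TD-like"))
  structure(list(pair = pair, band = band, lag_rad = lag_rad,
                 kappa = kappa, group = group),
            class = "coupling_spec")
}

#' Mean resultant length of the von Mises distribution
#'
#' `I1(kappa)/I0(kappa)`: the expected phase-locking value of a pair whose
#' phase difference is von Mises jittered with concentration `kappa`.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return Numeric vector in \[0, 1).
#' @export
vonmises_mean_resultant <- function(kappa) {
  ifelse(is.finite(kappa),
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE),
         1)
}

#' Configure a synthetic two-group EEG cohort
#'
#' The generated world: per channel, a sum of narrowband oscillations (one
#' per canonical band, sinusoid at the band centre with slowly drifting
#' Ornstein-Uhlenbeck phase) over 1/f background noise; selected pairs share
#' an oscillator with a lagged, von Mises-jittered phase; an instantaneous
#' mixing matrix emulates volume conduction.
#'
#' @param n_per_group subjects per group (>= 1).
#' @param channel_labels montage labels; default the 19-name 10-20 set.
#' @param fs sampling rate, Hz.
#' @param duration_s recording length per subject, seconds (>= 4).
#' @param band_amplitudes numeric array `2 x channels x 4` (groups ASD-like,
#'   TD-like x channel x band), oscillation amplitudes in microvolts;
#'   default [default_band_amplitudes()].
#' @param noise_exponent 1/f spectral slope of the background (default 1).
#' @param noise_rms background RMS amplitude, microvolts (default 10).
#' @param subject_cv between-subject coefficient of variation of a global
#'   per-subject amplitude scale (lognormal, default 0.2); emulates gain
#'   differences (skull, electrode contact) that per-segment rescaling is
#'   designed to remove.
#' @param topo_cv between-subject coefficient of variation of the
#'   per-channel/band amplitude topography (lognormal, default 0.07);
#'   this is the variability that survives min-max rescaling.
#' @param mixing channels x channels instantaneous mixing matrix (identity
#'   = no volume conduction).
#' @param couplings list of [coupling_spec()] objects.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 18L,
                       channel_labels = montage_1020(),
                       fs = 250, duration_s = 60,
                       band_amplitudes = NULL,
                       noise_exponent = 1, noise_rms = 10,
                       subject_cv = 0.2, topo_cv = 0.07,
                       mixing = NULL,
                       couplings = list(),
                       seed = 1L) {
  nch <- length(channel_labels)
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  if (duration_s < 4) stop("duration_s must be >= 4 (at least two 2-s epochs)")
  if (is.null(band_amplitudes))
    band_amplitudes <- default_band_amplitudes(channel_labels)
  stopifnot(length(dim(band_amplitudes)) == 3L,
            dim(band_amplitudes)[1] == 2L,
            dim(band_amplitudes)[2] == nch,
            dim(band_amplitudes)[3] == 4L)
  if (any(band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  if (is.null(mixing)) mixing <- diag(nch)
  if (!is.matrix(mixing) || nrow(mixing) != nch || ncol(mixing) != nch)
    stop("mixing must be a square ", nch, " x ", nch, " matrix")
  if (any(diag(mixing) <= 0)) stop("mixing must have a positive diagonal")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  seen <- character(0)
  for (cp in couplings) {
    stopifnot(inherits(cp, "coupling_spec"))
    bad <- setdiff(cp$pair, channel_labels)
    if (length(bad))
      stop("coupling references unknown channel label(s): ",
           paste(bad, collapse = ", "))
    grp <- if (cp$group == "both") c("ASD-like", "TD-like") else cp$group
    keys <- paste(rep(grp, each = 2L), cp$band, cp$pair, sep = "|")
    dup <- intersect(keys, seen)
    if (length(dup))
      stop("channel used by more than one coupling in the same band/group: ",
           paste(dup, collapse = "; "))
    seen <- c(seen, keys)
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         channel_labels = channel_labels, fs = fs,
         duration_s = duration_s, band_amplitudes = band_amplitudes,
         noise_exponent = noise_exponent, noise_rms = noise_rms,
         subject_cv = subject_cv, topo_cv = topo_cv, mixing = mixing,
         couplings = couplings, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default band amplitude topography
#'
#' Baseline oscillation amplitudes (microvolts) of theta/alpha/beta1/beta2
#' = 8/10/5/4 on every channel; the ASD-like group carries a +30% elevation
#' on the frontal set ([frontal_channels()]) in all four bands, giving the
#' group statistics a detectable, sign-correct frontal power effect.
#'
#' @param channel_labels montage labels.
#' @param frontal_boost multiplicative frontal elevation for the ASD-like
#'   group (default 1.3).
#' @return Array `2 x channels x 4` with dimnames.
#' @export
default_band_amplitudes <- function(channel_labels = montage_1020(),
                                    frontal_boost = 1.3) {
  base <- c(theta = 8, alpha = 10, beta1 = 5, beta2 = 4)
  nch <- length(channel_labels)
  amp <- array(rep(base, each = 2L * nch), dim = c(2L, nch, 4L),
               dimnames = list(c("ASD-like", "TD-like"), channel_labels,
                               names(base)))
  fr <- intersect(frontal_channels(), channel_labels)
  amp["ASD-like", fr, ] <- amp["ASD-like", fr, ] * frontal_boost
  amp
}

#' Default coupling set
#'
#' Fronto-parietal alpha and vertex low-beta couplings, stronger (higher
#' von Mises concentration) in the ASD-like group, plus a shared occipital
#' alpha coupling; lags are non-zero so both PLV and ciPLV can see them.
#'
#' @return List of [coupling_spec()] objects.
#' @export
default_couplings <- function() {
  list(
    coupling_spec(c("F3", "P3"), "alpha", pi / 4, 4, "ASD-like"),
    coupling_spec(c("F4", "P4"), "alpha", pi / 4, 4, "ASD-like"),
    coupling_spec(c("Cz", "Pz"), "beta1", pi / 4, 4, "ASD-like"),
    coupling_spec(c("F3", "P3"), "alpha", pi / 4, 1, "TD-like"),
    coupling_spec(c("F4", "P4"), "alpha", pi / 4, 1, "TD-like"),
    coupling_spec(c("Cz", "Pz"), "beta1", pi / 4, 1, "TD-like"),
    coupling_spec(c("O1", "O2"), "alpha", pi / 6, 3, "both")
  )
}

#' Default synthetic cohort preset
#'
#' 18 + 18 subjects, 19 channels at 250 Hz, frontal power elevation and
#' stronger fronto-parietal coupling in the ASD-like group.
#'
#' @param n_per_group subjects per group.
#' @param duration_s seconds per subject.
#' @param seed integer seed.
#' @param ... passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
default_cohort_config <- function(n_per_group = 18L, duration_s = 60,
                                  seed = 1L, ...) {
  sim_config(n_per_group = n_per_group, duration_s = duration_s,
             couplings = default_couplings(), seed = seed, ...)
}

# --- internal generators ----------------------------------------------------

# 1/f^alpha background noise, unit RMS, via spectrally shaped white noise
one_over_f_noise <- function(n, fs, exponent) {
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  mag <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- complex(real = rep(0, n))
  full[2L:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Ornstein-Uhlenbeck phase drift: stationary AR(1) in continuous time,
# relaxation rate lambda (1/s), stationary sd sd_st (rad)
ou_phase_drift <- function(n, fs, lambda = 0.2, sd_st = 1.5) {
  a <- exp(-lambda / fs)
  e <- stats::rnorm(n, 0, sd_st * sqrt(1 - a^2))
  e[1] <- stats::rnorm(1, 0, sd_st)
  as.numeric(stats::filter(e, a, method = "recursive"))
}

# full oscillator phase at band-centre frequency f0
oscillator_phase <- function(n, fs, f0) {
  2 * pi * f0 * (seq_len(n) - 1L) / fs +
    stats::runif(1, 0, 2 * pi) +
    ou_phase_drift(n, fs)
}

# von Mises quantile function (mean 0), vectorised over p
qvonmises <- function(p, kappa) {
  if (!is.finite(kappa) || kappa > 100) {
    # normal approximation; exact limit 0 for kappa = Inf
    if (!is.finite(kappa)) return(rep(0, length(p)))
    return(pmax(-pi, pmin(pi, stats::qnorm(p, 0, 1 / sqrt(kappa)))))
  }
  if (kappa < 1e-8) return((2 * p - 1) * pi)
  x <- seq(-pi, pi, length.out = 4001L)
  d <- exp(kappa * (cos(x) - 1))
  cdf <- cumsum(c(0, (d[-1] + d[-length(d)]) / 2)) * diff(x[1:2])
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, x, xout = p, rule = 2, ties = "ordered")$y
}

# smooth process with exact von Mises(0, kappa) marginal: low-pass Gaussian
# carrier (frequency-domain Gaussian of sigma bw_hz) pushed through the
# Gaussian copula to the von Mises quantile
smooth_vonmises_jitter <- function(n, fs, kappa, bw_hz = 2) {
  if (!is.finite(kappa)) return(rep(0, n))
  g <- stats::rnorm(n)
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1L), -1L)) * fs / n
  gain <- exp(-0.5 * (f / bw_hz)^2)
  g <- Re(stats::fft(stats::fft(g) * gain, inverse = TRUE)) / n
  g <- g / stats::sd(g)
  qvonmises(stats::pnorm(g), kappa)
}

# --- cohort generation ------------------------------------------------------

#' Generate a synthetic two-group EEG cohort
#'
#' Deterministic given `config$seed`. Each channel is the sum of four
#' band-centre oscillators with Ornstein-Uhlenbeck phase drift plus 1/f
#' noise; coupled pairs share an oscillator with a lagged, von Mises
#' jittered phase difference; the mixing matrix is applied instantaneously
#' last. A single eyes-closed interval spans the whole recording.
#'
#' @param config a [sim_config()].
#' @return List of `2 * n_per_group` [new_recording()] objects (ASD-like
#'   group first).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bands <- eeg_bands()
  labels <- config$channel_labels
  nch <- length(labels)
  n <- round(config$duration_s * config$fs)
  sdlog_g <- sqrt(log(1 + config$subject_cv^2))
  sdlog_t <- sqrt(log(1 + config$topo_cv^2))
  withr::with_seed(config$seed, {
    out <- list()
    for (g in c("ASD-like", "TD-like")) {
      for (s in seq_len(config$n_per_group)) {
        amp <- config$band_amplitudes[g, , ] *
          stats::rlnorm(1L, -sdlog_g^2 / 2, sdlog_g) *
          matrix(stats::rlnorm(nch * 4L, -sdlog_t^2 / 2, sdlog_t), nch, 4L)
        x <- matrix(0, nch, n)
        for (b in seq_len(4L)) {
          f0 <- bands$center[b]
          cps <- Filter(function(cp) cp$band == bands$name[b] &&
                          cp$group %in% c("both", g), config$couplings)
          coupled <- character(0)
          for (cp in cps) {
            i <- match(cp$pair[1], labels); j <- match(cp$pair[2], labels)
            phi <- oscillator_phase(n, config$fs, f0)
            eta <- smooth_vonmises_jitter(n, config$fs, cp$kappa)
            x[i, ] <- x[i, ] + amp[i, b] * cos(phi)
            x[j, ] <- x[j, ] + amp[j, b] * cos(phi - cp$lag_rad - eta)
            coupled <- c(coupled, cp$pair)
          }
          for (c_idx in which(!(labels %in% coupled))) {
            x[c_idx, ] <- x[c_idx, ] +
              amp[c_idx, b] * cos(oscillator_phase(n, config$fs, f0))
          }
        }
        if (config$noise_rms > 0) {
          for (c_idx in seq_len(nch)) {
            x[c_idx, ] <- x[c_idx, ] + config$noise_rms *
              one_over_f_noise(n, config$fs, config$noise_exponent)
          }
        }
        x <- config$mixing %*% x
        sid <- sprintf("%s%02d", if (g == "ASD-like") "ASD" else "TD", s)
        out[[sid]] <- new_recording(sid, x, labels, config$fs,
                                    group_label = g)
      }
    }
    out
  })
}
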