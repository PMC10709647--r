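# shared fixtures, all generated in code

# amplitudes with a single active band/channel set, zero elsewhere
amp_only <- function(..., value = 20) {
  amp <- array(0, c(2L, 19L, 4L),
               dimnames = list(c("ASD-like", "TD-like"), montage_1020(),
                               eeg_bands()$name))
  for (spec in list(...)) amp[, spec$ch, spec$band] <- value
  amp
}

# two-channel coupled-pair scenario for estimator-recovery checks
recovery_config <- function(kappa, duration_s = 120, seed = 42,
                            lag = pi / 4) {
  sim_config(n_per_group = 1L, duration_s = duration_s,
             band_amplitudes = amp_only(list(ch = c("C3", "P3"),
                                             band = "alpha")),
             noise_rms = 1, subject_cv = 0, topo_cv = 0,
             couplings = list(coupling_spec(c("C3", "P3"), "alpha",
                                            lag, kappa)),
             seed = seed)
}

# band-filter two channels of a recording and return their phases
pair_phases <- function(rec, chans, band_name = "alpha") {
  b <- eeg_bands()[eeg_bands()$name == band_name, ]
  spec <- design_bandpass(b$f_low, b$f_high, rec$fs, order = b$order)
  filt <- apply_filter(rec, spec)
  instantaneous_phase(filt$data[chans, , drop = FALSE])
}

# epoch-averaged PLV/ciPLV over 2-s windows, edges trimmed
epoch_avg <- function(ph, fs = 250, fun = plv, trim_s = 1) {
  sel <- (trim_s * fs + 1):(ncol(ph) - trim_s * fs)
  n_ep <- floor(length(sel) / (2 * fs))
  mean(vapply(seq_len(n_ep), function(e) {
    i0 <- sel[1] + (e - 1) * 2 * fs
    fun(ph[1, i0:(i0 + 2 * fs - 1)], ph[2, i0:(i0 + 2 * fs - 1)])
  }, numeric(1)))
}

# small separable Gaussian feature table (two clouds, 18 + 18)
separable_table <- function(n_per_group = 18L, p = 8L, delta = 3,
                            seed = 123) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_group * p), n_per_group),
               matrix(rnorm(n_per_group * p), n_per_group))
    x[seq_len(n_per_group), 1:2] <- x[seq_len(n_per_group), 1:2] + delta
    colnames(x) <- paste0("f", seq_len(p))
    eegfc:::new_feature_table(
      x, rep(c("ASD-like", "TD-like"), each = n_per_group), "toy")
  })
}

# tiny cohort for structural checks (fast)
tiny_cohort <- function(n_per_group = 2L, duration_s = 12, seed = 5) {
  generate_cohort(default_cohort_config(n_per_group = n_per_group,
                                        duration_s = duration_s,
                                        seed = seed))
}
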