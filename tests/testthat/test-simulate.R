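test_that("cohort generation is deterministic and well-formed", {
  cfg <- default_cohort_config(n_per_group = 2L, duration_s = 12, seed = 9)
  recs1 <- generate_cohort(cfg)
  recs2 <- generate_cohort(cfg)
  expect_length(recs1, 4L)
  expect_identical(recs1, recs2)
  r <- recs1[[1]]
  expect_s3_class(r, "eeg_recording")
  expect_identical(r$channel_labels, montage_1020())
  expect_identical(dim(r$data), c(19L, 3000L))
  expect_equal(r$eyes_closed, list(c(0, 12)))
  expect_setequal(vapply(recs1, `[[`, character(1), "group_label"),
                  c("ASD-like", "TD-like"))
})

test_that("coupling and config validation catch bad input", {
  expect_error(coupling_spec(c("C3", "C3"), "alpha", 0, 1), "distinct")
  expect_error(coupling_spec(c("C3", "P3"), "alpha", 0, -1), "kappa")
  expect_error(sim_config(couplings = list(
    coupling_spec(c("C3", "XX"), "alpha", 0, 1))), "XX")
  expect_error(sim_config(duration_s = 3), "duration")
  expect_error(sim_config(mixing = matrix(0, 19, 19)), "diagonal")
  # one channel may not join two couplings in the same band/group
  expect_error(sim_config(couplings = list(
    coupling_spec(c("C3", "P3"), "alpha", 0, 1),
    coupling_spec(c("C3", "O1"), "alpha", 0, 1))), "more than one coupling")
})

test_that("Welch band power grows monotonically with configured amplitude", {
  powers <- vapply(c(5, 10, 20), function(a) {
    cfg <- sim_config(n_per_group = 1L, duration_s = 12,
                      band_amplitudes = amp_only(list(ch = "O1",
                                                      band = "alpha"),
                                                 value = a),
                      noise_rms = 2, subject_cv = 0, topo_cv = 0, seed = 21)
    rec <- generate_cohort(cfg)[[1]]
    ep <- extract_epochs(rec)
    mean(vapply(seq_len(dim(ep$epochs)[1]), function(e) {
      band_power(welch_psd(ep$epochs[e, , ], rec$fs),
                 eeg_bands()[2, ])[match("O1", rec$channel_labels)]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
  # quadrupling amplitude ~ 4x power for the oscillator-dominated channel
  expect_gt(powers[3] / powers[1], 8)
})

test_that("von Mises jitter has the analytic mean resultant (MC oracle)", {
  # independent Monte-Carlo oracle: rejection sampling (Best & Fisher)
  rvm <- function(n, kappa) {
    out <- numeric(0)
    while (length(out) < n) {
      m <- 2 * n
      tau <- 1 + sqrt(1 + 4 * kappa^2)
      rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
      rr <- (1 + rho^2) / (2 * rho)
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      c_ <- kappa * (rr - f)
      keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
      out <- c(out, sign(u3[keep] - 0.5) * acos(f[keep]))
    }
    out[seq_len(n)]
  }
  withr::with_seed(77, {
    for (k in c(0.5, 4)) {
      mc <- Mod(mean(exp(1i * rvm(20000, k))))
      expect_equal(vonmises_mean_resultant(k), mc, tolerance = 0.02)
      # the generator's smooth jitter keeps the same marginal law
      eta <- eegfc:::smooth_vonmises_jitter(60000, 250, k)
      expect_lt(abs(Mod(mean(exp(1i * eta))) - vonmises_mean_resultant(k)),
                0.05)
    }
  })
})

test_that("kappa = Inf gives a constant lag and PLV = ciPLV = 1", {
  cfg <- recovery_config(Inf, duration_s = 20, lag = pi / 2)
  rec <- generate_cohort(cfg)[[1]]
  ph <- pair_phases(rec, c("C3", "P3"))
  sel <- 500:4500
  expect_gt(plv(ph[1, sel], ph[2, sel]), 0.99)
  expect_gt(ciplv(ph[1, sel], ph[2, sel]), 0.98)
})

test_that("plv estimator matches the iid-uniform independence null", {
  # E[PLV^2] = 1/T for T iid uniform phase differences
  withr::with_seed(11, {
    Tlen <- 500L
    plv2 <- replicate(300, plv(runif(Tlen, -pi, pi),
                               runif(Tlen, -pi, pi))^2)
    expect_equal(mean(plv2), 1 / Tlen, tolerance = 0.15)
  })
})

test_that("uncoupled simulator pairs sit far below coupled ones", {
  cfg <- recovery_config(8, duration_s = 60)
  rec <- generate_cohort(cfg)[[1]]
  # C3-P3 coupled; C3 vs an independent oscillator channel is not
  cfg2 <- sim_config(n_per_group = 1L, duration_s = 60,
                     band_amplitudes = amp_only(list(ch = c("C3", "P3"),
                                                     band = "alpha")),
                     noise_rms = 1, subject_cv = 0, topo_cv = 0, seed = 42)
  rec2 <- generate_cohort(cfg2)[[1]]
  ph_c <- pair_phases(rec, c("C3", "P3"))
  ph_u <- pair_phases(rec2, c("C3", "P3"))
  sel <- 500:14500
  expect_gt(plv(ph_c[1, sel], ph_c[2, sel]), 0.85)
  expect_lt(plv(ph_u[1, sel], ph_u[2, sel]), 0.3)
})
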