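test_that("welch_psd concentrates a tone and respects Parseval", {
  fs <- 250
  t <- (0:499) / fs
  tone <- sin(2 * pi * 10 * t)
  p <- welch_psd(matrix(tone, 1), fs)
  expect_equal(p$freq[which.max(p$psd)], 10)
  expect_gte(sum(p$psd[, p$freq >= 8 & p$freq <= 12]) / sum(p$psd), 0.95)
  # Parseval: integrated PSD ~ signal variance (A^2/2)
  expect_equal(sum(p$psd) * diff(p$freq[1:2]), 0.5, tolerance = 0.01)
  expect_true(all(welch_psd(matrix(0, 1, 500), fs)$psd == 0))
  expect_error(welch_psd(matrix(0, 1, 100), fs), "shorter than one Welch")
})

test_that("white-noise band powers are flat across equal-width bands", {
  withr::with_seed(8, {
    fs <- 250
    b1 <- list(f_low = 8, f_high = 12)
    b2 <- list(f_low = 30, f_high = 34)
    r <- rowMeans(replicate(400, {
      p <- welch_psd(matrix(rnorm(500), 1), fs)
      c(band_power(p, b1), band_power(p, b2))
    }))
    expect_equal(r[1] / r[2], 1, tolerance = 0.05)
  })
})

test_that("band_power selects inclusive grid bands and scales quadratically", {
  p <- list(freq = 0:20, psd = matrix(0, 1, 21))
  p$psd[1, 11] <- 6          # power only at 10 Hz
  expect_gt(band_power(p, list(f_low = 8, f_high = 12)), 0)
  expect_equal(band_power(p, list(f_low = 4, f_high = 7)), 0)
  expect_error(band_power(p, list(f_low = 30, f_high = 40)), "intersect")
  flat <- list(freq = 0:20, psd = matrix(3, 1, 21))
  expect_equal(band_power(flat, list(f_low = 4, f_high = 7)), 3)
  # doubling amplitude quadruples power
  fs <- 250; t <- (0:499) / fs
  p1 <- band_power(welch_psd(matrix(sin(2 * pi * 10 * t), 1), fs),
                   list(f_low = 8, f_high = 12))
  p2 <- band_power(welch_psd(matrix(2 * sin(2 * pi * 10 * t), 1), fs),
                   list(f_low = 8, f_high = 12))
  expect_equal(p2 / p1, 4, tolerance = 1e-10)
})

test_that("normalize_segment is a 0-1 rescale with a 0.5 degenerate case", {
  expect_equal(normalize_segment(c(3, 5, 7)), c(0, 0.5, 1))
  expect_equal(normalize_segment(rep(2.2, 18)), rep(0.5, 18))
  withr::with_seed(2, {
    v <- rnorm(18)
    out <- normalize_segment(v)
    expect_equal(range(out), c(0, 1))
    expect_equal(order(out), order(v))
  })
  expect_error(normalize_segment(c(1, NA, 3)), "non-finite")
})

test_that("subject spectral features are 18 x 4, bounded and scale-invariant", {
  recs <- tiny_cohort(n_per_group = 1L)
  prep <- preprocess_recording(recs[[1]])
  ep <- extract_epochs(prep)
  sf <- subject_spectral_features(ep)
  expect_identical(dim(sf$matrix), c(18L, 4L))
  expect_length(as.vector(sf$matrix), 72L)
  expect_true(all(sf$matrix >= 0 & sf$matrix <= 1))
  # single epoch: features equal that epoch's normalised band powers
  ep1 <- ep; ep1$epochs <- ep$epochs[1, , , drop = FALSE]
  sf1 <- subject_spectral_features(ep1)
  psd <- welch_psd(ep$epochs[1, , ], ep$fs)
  expect_equal(sf1$matrix[, "alpha"],
               normalize_segment(band_power(psd, eeg_bands()[2, ])),
               ignore_attr = TRUE)
  # global amplitude scaling leaves normalised features unchanged
  ep_scaled <- ep; ep_scaled$epochs <- 3.7 * ep$epochs
  expect_equal(subject_spectral_features(ep_scaled)$matrix, sf$matrix,
               tolerance = 1e-12)
})

test_that("frontal amplitude boost shows up in group-mean features", {
  recs <- generate_cohort(default_cohort_config(n_per_group = 3L,
                                                duration_s = 20, seed = 31))
  ft <- spectral_feature_table(recs)
  expect_identical(dim(ft$x), c(6L, 72L))
  fr_cols <- paste0(rep(intersect(frontal_channels(), montage_1020()), 4),
                    "_", rep(eeg_bands()$name, each = 7))
  fr_cols <- intersect(fr_cols, colnames(ft$x))
  ia <- ft$labels == "ASD-like"
  expect_gt(mean(ft$x[ia, fr_cols]), mean(ft$x[!ia, fr_cols]))
})
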