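test_that("design_bandpass honours explicit orders and the heuristic", {
  th <- design_bandpass(4, 7, 250, order = 24)
  expect_length(th$h, 25L)
  # -6 dB points bracket the passband
  resp <- function(s, f) abs(fir_response(s, f))
  expect_gt(resp(th, 4), 0.5)
  expect_gt(resp(th, 7), 0.5)
  # a 25-tap design is very soft: it has no usable low-side stopband at
  # all (the response even bulges slightly below the band), and its only
  # real attenuation is toward high frequencies
  expect_lt(resp(th, 30), 0.5)
  expect_lt(resp(th, 60), resp(th, 30))
  # heuristic: transition bandwidth max(0.25 * f_low, 2) = 2 Hz here
  bb <- design_bandpass(1, 45, 250)
  expect_equal(bb$transition_bw, 2)
  expect_equal(bb$fc_high, 46)
  expect_true(bb$order %% 2 == 0)
  # gain at band centre within 1% of unity
  al <- design_bandpass(8, 12, 250, order = 24)
  expect_equal(resp(al, 10), 1, tolerance = 0.01)
  expect_equal(resp(bb, 23), 1, tolerance = 0.01)
  expect_error(design_bandpass(40, 130, 250), "Nyquist")
  expect_error(design_bandpass(4, 7, 250, order = 25), "even")
})

test_that("apply_filter is zero-phase, length-preserving and linear", {
  fs <- 250
  t <- (0:7499) / fs
  al <- design_bandpass(8, 12, fs, order = 24)
  tone <- cos(2 * pi * 10 * t)
  rec <- new_recording("s", rbind(tone, tone), c("C3", "C4"), fs)
  out <- apply_filter(rec, al)
  expect_identical(dim(out$data), dim(rec$data))
  mid <- 1000:6000
  # in-band tone: amplitude within 1%, zero phase shift (max correlation
  # at lag 0)
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.01)
  cc <- stats::ccf(out$data[1, mid], tone[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # DC-only input is annihilated
  bb <- design_bandpass(1, 45, fs)
  dc <- new_recording("d", matrix(7.5, 2, 7500), c("C3", "C4"), fs)
  expect_lt(max(abs(apply_filter(dc, bb)$data)), 1e-6 * 7.5)

  # slow drift attenuated according to the computed response
  drift <- sin(2 * pi * 0.3 * t)
  rd <- new_recording("dr", rbind(drift, drift), c("C3", "C4"), fs)
  outd <- apply_filter(rd, bb)
  expect_equal(max(abs(outd$data[1, mid])),
               abs(fir_response(bb, 0.3)), tolerance = 0.05)

  # linearity
  withr::with_seed(3, {
    x <- rnorm(7500); y <- rnorm(7500)
    mk <- function(v) new_recording("l", matrix(v, 1), "Cz", fs)
    lhs <- apply_filter(mk(2 * x - 3 * y), bb)$data
    rhs <- 2 * apply_filter(mk(x), bb)$data - 3 * apply_filter(mk(y), bb)$data
    expect_equal(lhs, rhs, tolerance = 1e-10)
  })

  # too-short signal errors
  short <- new_recording("sh", matrix(rnorm(500), 1), "Cz", fs)
  expect_error(apply_filter(short, bb), "shorter than 3 x filter length")
  wrong_fs <- new_recording("w", matrix(rnorm(5000), 1), "Cz", 200)
  expect_error(apply_filter(wrong_fs, bb), "sampled at")
})

test_that("rereference_to_fz subtracts Fz and preserves channel differences", {
  withr::with_seed(4, {
    x <- matrix(rnorm(19 * 100), 19)
    rec <- new_recording("r", x, montage_1020(), 250)
    out <- rereference_to_fz(rec)
    expect_equal(nrow(out$data), 18L)
    expect_false("Fz" %in% out$channel_labels)
    # pairwise differences between non-reference channels unchanged
    expect_equal(out$data["C3", ] - out$data["C4", ],
                 rec$data["C3", ] - rec$data["C4", ])
    # all channels identical to Fz -> all-zero output
    same <- new_recording("z", matrix(rep(x[5, ], each = 19), 19,
                                      byrow = FALSE),
                          montage_1020(), 250)
    expect_true(all(abs(rereference_to_fz(same)$data) == 0))
    # already re-referenced input errors informatively
    expect_error(rereference_to_fz(out), "not present")
  })
})

test_that("extract_epochs tiles eyes-closed intervals, dropping remainders", {
  fs <- 250
  x <- matrix(rnorm(2 * 15 * fs), 2)
  mk <- function(iv) new_recording("e", x, c("C3", "C4"), fs,
                                   eyes_closed = iv)
  expect_equal(dim(extract_epochs(mk(list(c(0, 10))))$epochs), c(5, 2, 500))
  expect_equal(dim(extract_epochs(mk(list(c(0, 5.5))))$epochs)[1], 2L)
  two <- extract_epochs(mk(list(c(0, 3), c(10, 13))))
  expect_equal(dim(two$epochs)[1], 2L)
  # epoch count = sum over intervals of floor(length / epoch_s)
  iv <- list(c(0, 4.7), c(5, 11.2), c(12, 13))
  expect_equal(dim(extract_epochs(mk(iv))$epochs)[1],
               sum(vapply(iv, function(v) floor((v[2] - v[1]) / 2),
                          numeric(1))))
  expect_error(extract_epochs(mk(list(c(0, 1.5)))), "no eyes-closed")
  # epochs reproduce the underlying samples
  ep <- extract_epochs(mk(list(c(0, 4))))
  expect_equal(ep$epochs[2, , ], x[, 501:1000])
})
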