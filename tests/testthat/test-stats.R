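test_that("wilcoxon_ranksum matches hand and reference values", {
  # identical samples: no separation
  expect_gte(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p.value, 0.9)
  # enumeration by hand: a occupies the two smallest ranks in 1 of 10
  # subsets, two-tailed doubles it
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4, 5))$p.value, 0.2)
  # fully separated 18 vs 18: the normal approximation bottoms out at
  # z = (171 - 333 + 0.5) / sqrt(18 * 18 * 37 / 12) = -5.11
  sep <- wilcoxon_ranksum(1:18, 101:118)
  expect_equal(sep$p.value, 2 * pnorm(-161.5 / sqrt(18 * 18 * 37 / 12)))
  expect_lt(sep$p.value, 1e-6)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("exact path equals the independent reference for n <= 10", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      na <- sample(2:5, 1); nb <- sample(2:5, 1)
      a <- rnorm(na); b <- rnorm(nb)     # continuous: no ties
      ours <- wilcoxon_ranksum(a, b)
      expect_identical(ours$method, "exact")
      ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact tail for moderate n", {
  withr::with_seed(9, {
    a <- rnorm(10); b <- rnorm(10, 1)
    pn <- wilcoxon_ranksum(a, b, exact = FALSE)$p.value
    pe <- wilcoxon_ranksum(a, b, exact = TRUE)$p.value
    expect_equal(pn, pe, tolerance = 0.02)
  })
})

test_that("benjamini_hochberg reproduces the step-up rule", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh$adjusted, rep(0.04, 4))
  expect_true(all(bh$rejected))
  expect_false(any(benjamini_hochberg(rep(1, 5))$rejected))
  expect_equal(benjamini_hochberg(0.03)$adjusted, 0.03)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  # property: equality with the reference implementation, monotone after
  # sorting
  withr::with_seed(14, {
    for (rep in 1:10) {
      p <- runif(50)
      adj <- benjamini_hochberg(p)$adjusted
      expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
      expect_true(all(adj >= p - 1e-12))
    }
  })
})

test_that("friedman_test hits its closed-form extremes", {
  # perfect concordance: chi^2 = n (k - 1)
  n <- 18L; k <- 18L
  perfect <- matrix(rep(seq_len(k), each = n), n)
  perfect <- perfect + matrix(runif(n * k, 0, 0.1), n)  # keep order strict
  fr <- friedman_test(perfect)
  expect_equal(fr$statistic, n * (k - 1), tolerance = 1e-9)
  expect_equal(fr$df, 17L)
  # constant data: statistic 0, p = 1
  fc <- friedman_test(matrix(5, 6, 4))
  expect_equal(fc$statistic, 0)
  expect_equal(fc$p.value, 1)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("friedman_test agrees with the reference and is rank-invariant", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      m <- matrix(rnorm(8 * 5), 8)
      ours <- friedman_test(m)
      ref <- stats::friedman.test(m)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-12)
      # invariance under strictly monotone within-block transforms
      expect_equal(friedman_test(exp(m))$statistic, ours$statistic)
    }
  })
})

test_that("mass_univariate flags the right features with direction", {
  withr::with_seed(16, {
    n <- 18L
    x <- matrix(rnorm(2 * n * 20), 2 * n, 20)
    x[seq_len(n), 1:3] <- x[seq_len(n), 1:3] + 2.5   # ASD higher
    x[, 20] <- 1                                     # constant feature
    colnames(x) <- paste0("f", 1:20)
    labels <- rep(c("ASD-like", "TD-like"), each = n)
    st <- mass_univariate(x, labels)
    expect_s3_class(st, "stat_result")
    expect_true(all(st$significant[1:3]))
    expect_true(all(st$direction[1:3] == 1))
    expect_equal(st$p[20], 1)
    expect_false(st$significant[20])
    expect_true(all(st$p_adj >= st$p - 1e-12))
    expect_identical(st$significant, st$p_adj <= 0.05)
    expect_error(mass_univariate(x, rep("ASD-like", 2 * n)), "two groups")
    expect_error(mass_univariate(x[c(1, 19, 20, 21), ],
                                 labels[c(1, 19, 20, 21)]),
                 "at least 2 subjects")
  })
})

test_that("friedman_band_tests reports channel and group effects per band", {
  recs <- generate_cohort(default_cohort_config(n_per_group = 4L,
                                                duration_s = 12, seed = 19))
  ft <- spectral_feature_table(recs)
  fr <- friedman_band_tests(ft)
  expect_named(fr, eeg_bands()$name)
  expect_equal(fr$theta$channels$df, 17L)
  expect_equal(fr$theta$groups$df, 1L)
  expect_gte(fr$alpha$channels$statistic, 0)
})
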