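test_that("trimming keeps the central portion with floored boundaries", {
  x <- seq_len(1000)
  out <- trim_recording(x, 0.15)
  expect_length(out, 700)
  expect_equal(out[1], 151)       # floor(0.15 * 1000) = 150 removed
  expect_equal(out[700], 850)
  expect_identical(trim_recording(x, 0), x)
  expect_error(window_spec(trim_fraction = 0.5), class = "emgpr_config_error")
  expect_error(trim_recording(x, 0.5), class = "emgpr_config_error")
  ## matrix input trims rows
  m <- matrix(seq_len(20), ncol = 2)
  expect_equal(nrow(trim_recording(m, 0.2)), 6)
})

test_that("window count matches the floor formula and an enumeration oracle", {
  spec <- window_spec(window_length = 0.2, increment = 0.05)
  expect_equal(dim(slice_windows(rnorm(1000), spec, 1000))[3L], 17)
  expect_equal(dim(slice_windows(rnorm(700), spec, 1000))[3L], 11)
  expect_equal(dim(slice_windows(rnorm(200), spec, 1000))[3L], 1)  # L = w
  expect_error(slice_windows(rnorm(100), spec, 1000),
               class = "emgpr_config_error")
  ## property: formula == brute-force placement for many (L, w, i)
  withr::with_seed(1, {
    for (rep in 1:200) {
      L <- sample(3:500, 1); w <- sample(seq_len(L), 1)
      i <- sample(seq_len(w), 1)
      expect_identical(emgpr:::n_windows(L, w, i),
                       count_windows_oracle(L, w, i))
    }
  })
})

test_that("time-domain features match worked examples and the loop oracle", {
  expect_equal(unname(extract_td_features(c(5, 5, 5, 5))), c(5, 0, 0, 0))
  expect_equal(unname(extract_td_features(c(1, -1, 1, -1))), c(1, 6, 3, 2))
  expect_error(extract_td_features(c(1, 2)), class = "emgpr_data_error")
  withr::with_seed(2, {
    for (rep in 1:25) {
      x <- rnorm(sample(3:60, 1))
      zt <- runif(1, 0, 0.5); st <- runif(1, 0, 0.5)
      expect_equal(unname(extract_td_features(x, zt, st)),
                   unname(td_oracle(x, zt, st)))
    }
  })
})

test_that("features respond to sign flips as expected", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      x <- rnorm(50)
      expect_equal(extract_td_features(-x), extract_td_features(x))
    }
  })
})

test_that("an 8-channel window yields 32 concatenated features", {
  w <- matrix(rnorm(100 * 8), ncol = 8)
  f <- extract_td_features(w)
  expect_length(f, 32)
  expect_equal(unname(f[1:4]), unname(extract_td_features(w[, 1])))
})

test_that("fast segment extraction equals the per-window operation", {
  withr::with_seed(4, {
    x <- matrix(rnorm(300 * 3), ncol = 3)
    fast <- emgpr:::td_features_segment(x, w = 40L, i = 13L,
                                        zc_threshold = 0.1,
                                        ssc_threshold = 0.05)
    nw <- emgpr:::n_windows(300L, 40L, 13L)
    expect_equal(nrow(fast), nw)
    for (k in seq_len(nw)) {
      win <- x[((k - 1L) * 13L + 1L):((k - 1L) * 13L + 40L), ]
      expect_equal(unname(fast[k, ]),
                   unname(extract_td_features(win, 0.1, 0.05)))
    }
  })
})

test_that("normalizations have the promised training-column statistics", {
  expect_equal(unname(apply_normalization(
    matrix(c(0, 2)), fit_normalization(matrix(c(0, 2)), "zscore"))[, 1]),
    c(-1, 1) / sqrt(2))
  expect_equal(unname(apply_normalization(
    matrix(c(0, 2)), fit_normalization(matrix(c(0, 2)), "midrange0range2"))[, 1]),
    c(-1, 1))
  withr::with_seed(5, {
    x <- matrix(rnorm(200) * rep(c(1, 10, 100, 0.01), each = 50), ncol = 4)
    z <- apply_normalization(x, fit_normalization(x, "zscore"))
    expect_lt(max(abs(colMeans(z))), 1e-10)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
    m <- apply_normalization(x, fit_normalization(x, "midrange0range2"))
    expect_equal(unname(apply(m, 2, min)), rep(-1, 4))
    expect_equal(unname(apply(m, 2, max)), rep(1, 4))
  })
  ## degenerate column: scale forced to 1 with a warning
  xd <- cbind(rnorm(10), 3)
  expect_warning(spec <- fit_normalization(xd, "zscore"), "zero-spread")
  expect_equal(unname(spec$scale[2]), 1)
})

test_that("session feature extraction yields the derived window counts", {
  fm <- tiny_fm()
  ## 500 Hz, 1 s reps trimmed 15% -> 350 samples; w=100, i=25 -> 11/rep
  expect_equal(sum(fm$class_index == 0L), 2 * 11)
  expect_equal(ncol(fm$values), 8 * 4)
  expect_equal(nrow(fm$values), 27 * 22)
  expect_true(all(is.finite(fm$values)))
  expect_equal(nrow(fm$labels), 27)
})
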