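test_that("filter banks satisfy the orthogonal QMF constraints", {
  for (w in c("db1", "db2", "db4", "db8")) {
    f <- wavelet_filters(w)
    L <- f$length
    expect_equal(sum(f$rec_lo), sqrt(2), tolerance = 1e-12)
    expect_equal(sum(f$rec_lo^2), 1, tolerance = 1e-12)
    # orthogonality to even shifts
    for (s in seq_len(L / 2 - 1)) {
      shifted <- c(rep(0, 2 * s), f$rec_lo[seq_len(L - 2 * s)])
      expect_equal(sum(f$rec_lo * shifted), 0, tolerance = 1e-12)
    }
    expect_equal(sum(f$rec_hi), 0, tolerance = 1e-12)
    expect_equal(sum(f$rec_lo * f$rec_hi), 0, tolerance = 1e-12)
  }
  expect_error(wavelet_filters("db3"), "unknown wavelet")
})

test_that("zero and constant signals decompose as linearity predicts", {
  dec <- dwt_decompose(numeric(5000), 6)
  expect_true(all(dec$approx == 0))
  expect_true(all(vapply(dec$details, function(d) all(d == 0), logical(1))))

  c0 <- 3.7
  dec <- dwt_decompose(rep(c0, 5000), 3)
  expect_lt(max(abs(unlist(dec$details))), 1e-10 * abs(c0))
  expect_gt(max(abs(dec$approx)), 0)
})

test_that("decomposition matches the direct-convolution oracle", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(64)
    dec <- dwt_decompose(x, 2, "db8")
    ora <- oracle_dwt_multilevel(x, 2, "db8")
    expect_lt(max(abs(dec$approx - ora$approx)), 1e-10)
    expect_lt(max(abs(dec$details[[1]] - ora$details[[1]])), 1e-10)
    expect_lt(max(abs(dec$details[[2]] - ora$details[[2]])), 1e-10)
  }
})

test_that("rebuild inverts decompose across lengths, wavelets and modes", {
  set.seed(7)
  for (n in c(32, 61, 100, 500, 1777, 5000)) {
    for (w in c("db1", "db8")) {
      ml <- max_decomposition_level(n, w)
      if (ml < 1) next
      x <- rnorm(n)
      for (m in c("symmetric", "antireflect", "periodic")) {
        dec <- dwt_decompose(x, min(4, ml), w, mode = m)
        err <- max(abs(dwt_rebuild(dec) - x)) / max(abs(x))
        expect_lt(err, 1e-8)
      }
    }
  }
})

test_that("decomposition is linear in the signal", {
  set.seed(11)
  x <- rnorm(300)
  y <- rnorm(300)
  a <- 2.5
  b <- -1.3
  d1 <- dwt_decompose(a * x + b * y, 3)
  dx <- dwt_decompose(x, 3)
  dy <- dwt_decompose(y, 3)
  expect_lt(max(abs(d1$approx - (a * dx$approx + b * dy$approx))), 1e-10)
  for (j in 1:3) {
    expect_lt(max(abs(d1$details[[j]] -
                        (a * dx$details[[j]] + b * dy$details[[j]]))), 1e-10)
  }
})

test_that("periodic extension conserves coefficient energy on even lengths", {
  set.seed(3)
  x <- rnorm(1000)
  dec <- dwt_decompose(x, 3, "db8", mode = "periodic")
  e <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
  expect_equal(e / sum(x^2), 1, tolerance = 0.01)
})

test_that("a 0.25 Hz tone concentrates in the d5/d6/a6 bands at 20 Hz", {
  x <- sin(2 * pi * 0.25 * (0:4999) / 20)
  dec <- dwt_decompose(x, 6)
  e_all <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
  e_band <- sum(dec$approx^2) + sum(dec$details[[5]]^2) + sum(dec$details[[6]]^2)
  expect_gt(e_band / e_all, 0.8)
})

test_that("maximum admissible level follows the dyadic rule", {
  expect_identical(max_decomposition_level(5000, "db8"), 8L)
  expect_identical(max_decomposition_level(5000, "db1"), 12L)
  expect_identical(max_decomposition_level(16, "db8"), 0L)
  expect_error(max_decomposition_level(15, "db8"), "filter length")
})

test_that("invalid decompositions are rejected with informative errors", {
  expect_error(dwt_decompose(rnorm(100), 10), "maximum admissible level")
  expect_error(dwt_decompose(c(rnorm(99), NA), 2), "non-finite")
  expect_error(dwt_decompose(rnorm(8), 1, "db8"), "at least 16")
  expect_error(dwt_decompose(rnorm(100), 0), "positive integer")
})

test_that("coefficient masking zeroes the requested content", {
  set.seed(5)
  x <- rnorm(5000)
  dec <- dwt_decompose(x, 4)

  all_zero <- dwt_rebuild(dec, coef_mask(zero_approx = TRUE,
                                         zero_details = 1:4))
  expect_identical(all_zero, numeric(5000))

  # zeroing a_L alone equals x minus the a_L-only rebuild (synthesis linearity)
  no_approx <- dwt_rebuild(dec, coef_mask(zero_approx = TRUE))
  approx_only <- dwt_rebuild(dec, coef_mask(zero_details = 1:4))
  expect_lt(max(abs(no_approx - (x - approx_only))), 1e-8)

  expect_error(dwt_rebuild(dec, coef_mask(zero_details = 5)),
               "only 4 levels")
  expect_error(coef_mask(thresholds = c("1" = -0.1)), "nonnegative")
  expect_error(coef_mask(zero_details = 0), ">= 1")
})

test_that("threshold masks suppress only above-threshold coefficients", {
  set.seed(9)
  x <- rnorm(500)
  dec <- dwt_decompose(x, 2)
  tau <- unname(stats::quantile(abs(dec$details[[1]]), 0.9))
  out <- dwt_rebuild(dec, coef_mask(thresholds = c("1" = tau)))
  dec2 <- dwt_decompose(out, 2)
  # re-decomposed detail should have no coefficient far above tau
  expect_lt(max(abs(dec2$details[[1]])), tau * 1.5)
  # sub-threshold-only signal passes unchanged
  keep <- dec
  keep$details[[1]][abs(keep$details[[1]]) > tau] <- 0
  y <- dwt_rebuild(keep)
  expect_lt(max(abs(out - y)), 1e-10)
})

test_that("decompositions survive a JSON round trip", {
  set.seed(13)
  x <- rnorm(200)
  dec <- dwt_decompose(x, 3)
  path <- tempfile(fileext = ".json")
  decomposition_to_json(dec, path)
  back <- decomposition_from_json(path)
  expect_equal(back$approx, dec$approx, tolerance = 1e-12)
  expect_identical(back$levels, dec$levels)
  expect_lt(max(abs(dwt_rebuild(back) - x)), 1e-8)
  unlink(path)
})
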