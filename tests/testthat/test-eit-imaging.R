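model <- test_model()

test_that("the sensitivity matrix is reciprocal", {
  ch <- model$channels
  J <- model$jacobian
  worst <- 0
  for (r in seq_len(nrow(ch))) {
    r2 <- which(ch$drive == ch$meas[r] & ch$meas == ch$drive[r])
    if (length(r2) != 1L) next
    rel <- max(abs(J[r, ] - J[r2, ])) / max(abs(J[r, ]))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("zero voltage difference reconstructs to an exactly zero image", {
  img <- reconstruct(model, model$baseline, model$baseline)
  expect_true(all(img$pixels[model$mask] == 0))
  expect_true(all(is.na(img$pixels[!model$mask])))
})

test_that("the forward map is linear with 208 channels per frame", {
  expect_identical(length(model$baseline), 208L)
  ds <- numeric(model$n_elements)
  expect_identical(forward_frame(model, ds), numeric(208))
  set.seed(14)
  ds <- rnorm(model$n_elements)
  expect_equal(forward_frame(model, 2 * ds), 2 * forward_frame(model, ds),
               tolerance = 1e-12)
  expect_error(forward_frame(model, numeric(10)), "length")
})

test_that("an inclusion near an electrode dominates adjacent channels", {
  # small perturbation near electrode 1 (angle 0)
  near <- which((model$centroids[, 1] - 0.85)^2 +
                  model$centroids[, 2]^2 < 0.1^2)
  ds <- numeric(model$n_elements)
  ds[near] <- 1
  v <- forward_frame(model, ds)
  top <- model$channels[which.max(abs(v)), ]
  expect_true(top$drive %in% c(15, 16, 1, 2) || top$meas %in% c(15, 16, 1, 2))
})

test_that("an off-centre inclusion is localized by the reconstruction", {
  incl <- which((model$centroids[, 1] - 0.4)^2 +
                  model$centroids[, 2]^2 < 0.3^2)
  ds <- numeric(model$n_elements)
  ds[incl] <- -1
  img <- reconstruct(model, model$baseline + forward_frame(model, ds),
                     model$baseline)
  v <- img$pixels
  v[!model$mask] <- 0
  gx <- (seq_len(32) - 0.5) / 16 - 1
  X <- matrix(rep(gx, times = 32), 32)
  Y <- matrix(rep(gx, each = 32), 32)
  w <- abs(v) / sum(abs(v))
  cx <- sum(w * X)
  cy <- sum(w * Y)
  expect_lt(abs(atan2(cy, cx)), 30 * pi / 180)
  expect_lt(abs(sqrt(cx^2 + cy^2) - 0.4), 0.25)
})

test_that("reconstruction is linear in the voltage difference", {
  set.seed(15)
  d <- rnorm(208) * 1e-3
  i1 <- reconstruct(model, model$baseline + d, model$baseline)
  i2 <- reconstruct(model, model$baseline + 2 * d, model$baseline)
  expect_equal(i2$pixels[model$mask], 2 * i1$pixels[model$mask],
               tolerance = 1e-10)
  expect_error(reconstruct(model, c(NA, model$baseline[-1]),
                           model$baseline), "non-finite")
  expect_error(reconstruct(model, numeric(10), model$baseline), "208")
})

test_that("stronger regularization shrinks the inverse monotonically", {
  norms <- vapply(c(1e-4, 1e-3, 1e-2), function(a) {
    sqrt(sum(update_alpha(model, a)$inverse^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("series reconstruction honours the reference policy", {
  set.seed(16)
  data <- matrix(rep(model$baseline, each = 4), 4, 208) +
    rbind(0, matrix(rnorm(3 * 208) * 1e-3, 3, 208))
  fr <- frame_series(data, 20)
  imgs <- reconstruct_series(model, fr)
  expect_length(imgs, 4)
  expect_true(all(imgs[[1]]$pixels[model$mask] == 0))
  expect_identical(attr(imgs, "reference_policy"), "first_frame")

  const <- frame_series(matrix(rep(model$baseline, each = 3), 3, 208), 20)
  imgs_c <- reconstruct_series(model, const)
  expect_true(all(vapply(imgs_c, function(im) {
    all(im$pixels[model$mask] == 0)
  }, logical(1))))

  imgs_m <- reconstruct_series(model, fr, "mean_window", window = 1:2)
  expect_length(imgs_m, 4)
})

test_that("model construction validates its arguments", {
  expect_error(build_sensitivity(100), ">= 200")
  expect_error(build_sensitivity(800, alpha = 0), "positive")
  expect_error(update_alpha(model, -1), "positive")
})

test_that("images round-trip through CSV with nan off-mask", {
  img <- reconstruct(model, model$baseline + model$inverse[1, ] * 0 +
                       c(rep(1e-3, 10), numeric(198)), model$baseline)
  path <- tempfile(fileext = ".csv")
  write_image_csv(img, path)
  expect_true(any(grepl("nan", readLines(path))))
  back <- read_image_csv(path)
  expect_equal(back$pixels[model$mask], img$pixels[model$mask],
               tolerance = 1e-12)
  unlink(path)
})
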