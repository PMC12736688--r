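test_that("quality masking follows the mask set exactly", {
  doys <- c(152, 157, 162, 167, 172, 177)
  v <- seq(0.1, 0.6, by = 0.1)
  ms <- apply_quality_mask(v, doys, c(4L, 3L, 8L, 9L, 10L, 4L),
                           mask_set = c(3L, 8L, 9L, 10L))
  expect_equal(ms$valid, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(ms$values, v)  # values untouched
  all_clear <- apply_quality_mask(v, doys, rep(4L, 6))
  expect_true(all(all_clear$valid))
  identity <- apply_quality_mask(v, doys, c(3L, 8L, 9L, 9L, 10L, 11L),
                                 mask_set = integer(0))
  expect_true(all(identity$valid))
  expect_error(apply_quality_mask(v, doys, 1:3), "length")
})

test_that("Savitzky-Golay reproduces low-degree polynomials exactly", {
  t <- sort(c(seq(152, 300, by = 6), 155, 171))  # irregular grid
  const <- masked_series(rep(0.42, length(t)), t)
  expect_equal(sg_smooth(const)$values, const$values, tolerance = 1e-12)
  line <- masked_series(2 + 0.1 * t, t)
  expect_lt(max(abs(sg_smooth(line, 7, 2)$values - line$values)), 1e-9)
  quad <- masked_series(1 - 0.01 * t + 2e-4 * t^2, t)
  expect_lt(max(abs(sg_smooth(quad, 7, 2)$values - quad$values)), 1e-9)
})

test_that("Savitzky-Golay agrees with the classical filter on uniform grids", {
  skip_if_not_installed("signal")
  t <- seq(152, 302, by = 5)
  set.seed(21)
  y <- sin(2 * pi * t / 150) + rnorm(length(t), 0, 0.05)
  ours <- sg_smooth(masked_series(y, t), window = 7, polyorder = 2)$values
  ref <- signal::sgolayfilt(y, p = 2, n = 7)
  # interiors must agree exactly; boundary policies differ by construction
  core <- 4:(length(t) - 3)
  expect_lt(max(abs(ours[core] - ref[core])), 1e-9)
})

test_that("smoothing reduces noise on a seeded sine series", {
  t <- seq(1, 31) * 5 + 120
  truth <- 0.5 + 0.3 * sin(2 * pi * t / 200)
  set.seed(33)
  noisy <- truth + rnorm(31, 0, 0.05)
  sm <- sg_smooth(masked_series(noisy, t), 7, 2)$values
  expect_lt(sqrt(mean((sm - truth)^2)), sqrt(mean((noisy - truth)^2)))
})

test_that("too few valid points degrades to a warning no-op", {
  ms <- masked_series(c(1, 2, 3), c(10, 20, 30))
  expect_warning(out <- sg_smooth(ms, window = 7), "unsmoothed")
  expect_equal(out$values, ms$values)
})

test_that("harmonic regression recovers a noiseless cosine exactly", {
  set.seed(4)
  t <- sort(sample(1:365, 20))
  y <- 0.5 + 0.3 * cos(2 * pi * t / 365)
  fit <- harmonic_fit(masked_series(y, t), K = 1)
  expect_equal(unname(fit$a0), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$a[1]), 0.3, tolerance = 1e-8)
  expect_equal(unname(fit$b[1]), 0, tolerance = 1e-8)
  const <- harmonic_fit(masked_series(rep(0.7, 10), seq(10, 300, length.out = 10)))
  expect_equal(unname(const$a0), 0.7, tolerance = 1e-10)
  expect_lt(max(abs(c(const$a, const$b))), 1e-10)
})

test_that("gap filling interpolates the underlying curve and preserves data", {
  set.seed(5)
  t <- seq(5, 360, by = 12)
  y <- 0.5 + 0.3 * cos(2 * pi * t / 365) - 0.1 * sin(4 * pi * t / 365)
  valid <- runif(length(t)) > 0.3
  valid[c(1, length(t))] <- TRUE
  ms <- masked_series(y, t, valid)
  out <- harmonic_fit_fill(ms, K = 2)
  expect_lt(max(abs(out$filled[!valid] - y[!valid])), 1e-6)
  expect_identical(out$filled[valid], y[valid])
})

test_that("degenerate harmonic designs raise informative errors", {
  few <- masked_series(c(0.1, 0.2, 0.3), c(10, 50, 90))
  expect_error(harmonic_fit(few, K = 2, label = "sample 7"), "sample 7")
  expect_error(harmonic_fit(few, K = 2), "3 valid observations")
})

test_that("scene reconstruction tracks the noiseless truth through clouds", {
  sc <- small_scene(n_polygons = 30, seed = 14, gap_rate = 0.4)
  recon <- reconstruct_scene(sc)
  rice <- which(sc$class == "rice")
  cors <- vapply(rice, function(i)
    cor(recon$index$ndvi[i, ], sc$truth$ndvi[i, ]), numeric(1))
  expect_gt(min(cors), 0.95)
  # gap filling never alters valid (smoothed) observations: refilling with a
  # different gap pattern leaves commonly-valid slots identical
  expect_equal(dim(recon$valid), dim(sc$quality))
  expect_equal(recon$fill_fraction, rowMeans(sc$quality != 4L))
})
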