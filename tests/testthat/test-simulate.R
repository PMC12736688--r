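doys_default <- seq(152, 304, by = 5)

test_that("rice trajectory hits the parameterized endpoints", {
  p <- phenology_params(transplant_doy = 165, transplant_len = 15,
                        growth_len = 60, ripen_len = 40)
  fine <- 150:310
  set.seed(1)
  tr <- simulate_trajectory("rice", p, doys = fine, noise_sd = 0)
  expect_equal(tr$ndvi[fine == 165], p$ndvi_base, tolerance = 0.03)
  expect_equal(tr$ndvi[fine == 230], p$ndvi_peak, tolerance = 0.05)
  expect_lt(tr$ndvi[fine == 300], tr$ndvi[fine == 230])
  # flooded at transplanting, drained at harvest
  expect_equal(tr$lswi[fine == 165], p$lswi_flood, tolerance = 0.03)
  expect_equal(tr$lswi[fine == 305], p$lswi_dry, tolerance = 0.03)
})

test_that("water template is constant and non-vegetated", {
  tr <- simulate_trajectory("water", doys = doys_default, noise_sd = 0)
  expect_true(all(tr$ndvi <= 0))
  expect_equal(diff(range(tr$ndvi)), 0)
})

test_that("rice NDVI rises through growth and declines through ripening", {
  # oracle: numerical differencing of the noiseless curve on the revisit grid
  p <- phenology_params()
  tr <- simulate_trajectory("rice", p, doys = doys_default, noise_sd = 0)
  d <- diff(tr$ndvi)
  growth <- c(p$transplant_doy + p$transplant_len,
              p$transplant_doy + p$transplant_len + p$growth_len)
  ripen <- c(growth[2], growth[2] + p$ripen_len)
  lo <- doys_default[-length(doys_default)]
  hi <- doys_default[-1]
  in_growth <- lo >= growth[1] & hi <= growth[2]
  in_ripen <- lo >= ripen[1] & hi <= ripen[2]
  expect_gt(sum(in_growth), 10)
  expect_gt(sum(in_ripen), 3)
  expect_true(all(d[in_growth] > 0))
  expect_true(all(d[in_ripen] < 0))
})

test_that("unknown class names are rejected", {
  expect_error(simulate_trajectory("soybean", doys = doys_default),
               "unknown class")
})

test_that("band inversion reproduces the requested indices", {
  expect_equal(invert_bands(0, 0, 0.4),
               list(B2 = 0.04, B4 = 0.4, B8 = 0.4, B11 = 0.4))
  expect_equal(invert_bands(0.6, 0, 0.5)$B4, 0.5 * 0.4 / 1.6,
               tolerance = 1e-12)
  # round trip over the admissible range
  set.seed(3)
  nd <- runif(300, -0.8, 0.9)
  lw <- runif(300, -0.8, 0.9)
  b <- invert_bands(nd, lw, b8_profile = 0.1)  # low B8: no clipping over the range
  expect_lt(max(abs(as.numeric(ndvi(b$B8, b$B4)) - nd)), 1e-9)
  expect_lt(max(abs(as.numeric(lswi(b$B8, b$B11)) - lw)), 1e-9)
  expect_error(invert_bands(-1, 0, 0.4), "strictly inside")
})

test_that("gap injection matches its Bernoulli rate and keeps one clear step", {
  q <- matrix(4L, 10, 12)
  expect_identical(inject_gaps(q, 0), q)
  expect_error(inject_gaps(q, 1), "gap_rate")
  set.seed(9)
  big <- inject_gaps(matrix(4L, 10000, 30), 0.3)
  frac <- mean(big == 9L)
  expect_gt(frac, 0.29); expect_lt(frac, 0.31)
  expect_true(all(rowSums(big == 4L) >= 1))
  # extreme rate still leaves a valid observation everywhere
  set.seed(10)
  extreme <- inject_gaps(matrix(4L, 200, 5), 0.99)
  expect_true(all(rowSums(extreme == 4L) >= 1))
  # determinism under a fixed seed
  set.seed(11); a <- inject_gaps(q, 0.4)
  set.seed(11); b <- inject_gaps(q, 0.4)
  expect_identical(a, b)
})

test_that("scene construction counts samples and polygons correctly", {
  cfg <- scene_config(n_polygons = 20, points_per_polygon = 3, seed = 1,
                      classes = list(
                        rice = list(n_polygons = 10,
                                    template = default_class_templates()$rice),
                        water = list(n_polygons = 10,
                                     template = default_class_templates()$water)))
  sc <- build_dataset(cfg)
  expect_equal(dim(sc$bands)[1], 60)
  expect_equal(length(unique(sc$polygon_id)), 20)
  expect_equal(sum(sc$label), 30)
  expect_error(scene_config(classes = list(
    rice = list(n_polygons = 0, template = default_class_templates()$rice))),
    "at least one polygon")
})

test_that("default class mix is binary-balanced", {
  cfg <- scene_config(n_polygons = 100, seed = 1)
  np <- vapply(cfg$classes, function(x) x$n_polygons, numeric(1))
  expect_equal(sum(np), 100)
  expect_equal(unname(np["rice"]), 50)
  sc <- build_dataset(cfg)
  expect_equal(mean(sc$label), 0.5)
})

test_that("generated scenes satisfy the physical invariants", {
  sc <- small_scene(n_polygons = 40, seed = 2)
  expect_true(all(sc$bands >= 0 & sc$bands <= 1))
  nd <- ndvi(sc$bands[, , "B8"], sc$bands[, , "B4"])
  lw <- lswi(sc$bands[, , "B8"], sc$bands[, , "B11"])
  expect_true(all(abs(nd) <= 1) && all(abs(lw) <= 1))
  # class-conditional separability of the noiseless truth at peak season
  peak <- sc$doys >= 215 & sc$doys <= 265
  rice_peak <- mean(sc$truth$ndvi[sc$class == "rice", peak])
  water_peak <- mean(sc$truth$ndvi[sc$class == "water", peak])
  urban_peak <- mean(sc$truth$ndvi[sc$class == "urban", peak])
  expect_gt(rice_peak, water_peak + 0.5)
  expect_gt(rice_peak, urban_peak + 0.4)
})

test_that("scenes are reproducible and serialize byte-identically", {
  a <- small_scene(n_polygons = 30, seed = 123)
  b <- small_scene(n_polygons = 30, seed = 123)
  expect_identical(a$bands, b$bands)
  expect_identical(a$quality, b$quality)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_scene_csv(a, fa); write_scene_csv(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  unlink(c(fa, fb))
})

test_that("polygon points are correlated but not identical", {
  sc <- small_scene(n_polygons = 40, seed = 4, gap_rate = 0)
  nd <- ndvi(sc$bands[, , "B8"], sc$bands[, , "B4"])
  nd <- matrix(nd, nrow = dim(sc$bands)[1])
  rice <- which(sc$class == "rice")
  same_poly <- rice[sc$polygon_id[rice] == sc$polygon_id[rice[1]]]
  other_poly <- rice[sc$polygon_id[rice] != sc$polygon_id[rice[1]]][1:2]
  d_within <- mean(abs(nd[same_poly[1], ] - nd[same_poly[2], ]))
  d_between <- mean(abs(nd[same_poly[1], ] - nd[other_poly[1], ]))
  expect_gt(d_within, 0)            # independent pixel noise
  expect_lt(d_within, d_between + 0.05)  # shared polygon phenology
})
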