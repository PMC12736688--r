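test_that("group split is exact, stratified and polygon-pure", {
  sc <- small_scene(n_polygons = 100, seed = 6)
  sp <- group_split(sc$polygon_id, sc$label, test_fraction = 0.2, seed = 3)
  expect_length(sp$train, 240)
  expect_length(sp$test, 60)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(unique(sc$polygon_id[sp$train]),
                          unique(sc$polygon_id[sp$test])), 0)
  # stratified: half of the test polygons are rice
  expect_equal(mean(sc$label[sp$test]), 0.5, tolerance = 0.01)
  # deterministic per seed
  sp2 <- group_split(sc$polygon_id, sc$label, test_fraction = 0.2, seed = 3)
  expect_identical(sp$test, sp2$test)
})

test_that("no polygon straddles the split over many seeds", {
  sc <- small_scene(n_polygons = 40, seed = 7)
  for (seed in 1:500) {
    sp <- group_split(sc$polygon_id, sc$label, test_fraction = 0.3,
                      seed = seed)
    expect_length(intersect(unique(sc$polygon_id[sp$train]),
                            unique(sc$polygon_id[sp$test])), 0)
  }
})

test_that("degenerate splits are rejected", {
  expect_error(group_split(rep(1, 6), rep(0:1, 3)), "label-pure")
  expect_error(group_split(c(1, 1, 2, 2), c(0, 0, 1, 1), seed = 1),
               "at least 2 polygons")
})

test_that("the classifier fits linearly separable trajectories", {
  fs <- make_separable_set(N = 200)
  m <- sits_former(tiny_config(), seed = 1)
  m <- train_sits_former(m, fs, train_config(epochs = 20, seed = 1))
  expect_gt(utils::tail(m$history$acc, 1), 0.99)
  # first-epoch loss starts near chance level for balanced classes
  expect_equal(m$history$loss[1], log(2), tolerance = 0.15)
  expect_true(m$trained)
})

test_that("training is reproducible given the seed", {
  fs <- make_separable_set(N = 96)
  run <- function() {
    m <- sits_former(tiny_config(), seed = 5)
    train_sits_former(m, fs, train_config(epochs = 4, seed = 9))
  }
  a <- run(); b <- run()
  expect_identical(utils::tail(a$history$loss, 1),
                   utils::tail(b$history$loss, 1))
  expect_identical(a$theta, b$theta)
})

test_that("gradient clipping and schedulers are active and logged", {
  fs <- make_separable_set(N = 96)
  m <- sits_former(tiny_config(), seed = 2)
  tc <- train_config(epochs = 5, seed = 1, scheduler = "cosine")
  m <- train_sits_former(m, fs, tc)
  expect_gte(m$history$clip_count, 0)
  # cosine annealing decays the learning rate monotonically
  expect_true(all(diff(m$history$lr) <= 1e-12))
  expect_lt(utils::tail(m$history$lr, 1), tc$lr)
  # plateau scheduler carves a validation split and logs its metrics
  m2 <- sits_former(tiny_config(), seed = 2)
  m2 <- train_sits_former(m2, fs,
                          train_config(epochs = 3, seed = 1,
                                       scheduler = "plateau"))
  expect_length(m2$history$val_loss, 3)
})

test_that("standardization statistics come from the training split only", {
  fs <- make_separable_set(N = 120)
  sp <- group_split(fs$polygon_id, fs$label, test_fraction = 0.25, seed = 2)
  fs_train <- ricesits:::subset_features(fs, sp$train)
  fs_test <- ricesits:::subset_features(fs, sp$test)
  m <- sits_former(tiny_config(), seed = 3)
  m <- train_sits_former(m, fs_train, train_config(epochs = 2, seed = 1))
  expect_identical(m$standardizer$mean,
                   fit_standardizer(fs_train)$mean)
  std_all <- fit_standardizer(fs)
  expect_false(isTRUE(all.equal(m$standardizer$mean, std_all$mean)))
  # prediction standardizes test data with the frozen training statistics
  expect_silent(predict(m, fs_test))
})

test_that("temporal-mean logistic baseline beats chance but not the transformer setup", {
  sc <- small_scene(n_polygons = 60, seed = 21)
  fs <- featurize_scene(reconstruct_scene(sc), preset = "baseline")
  sp <- group_split(fs$polygon_id, fs$label, test_fraction = 0.25, seed = 1)
  bl <- temporal_mean_logistic(ricesits:::subset_features(fs, sp$train),
                               ricesits:::subset_features(fs, sp$test))
  acc <- mean(bl$class == fs$label[sp$test])
  expect_gt(acc, 0.6)
  expect_length(bl$prob, length(sp$test))
})

test_that("checkpoints restore bit-identical forward outputs", {
  fs <- make_separable_set(N = 64)
  m <- sits_former(tiny_config(), seed = 4)
  m <- train_sits_former(m, fs, train_config(epochs = 2, seed = 1))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_identical(predict(m, fs), predict(back, fs))
  expect_identical(back$standardizer$mean, m$standardizer$mean)
  expect_error(suppressWarnings(load_checkpoint(tempfile())))
  unlink(f)
})
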