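test_that("forward pass produces normalized, deterministic probabilities", {
  fs <- make_feature_set(N = 6, T_ = 9, C = 3)
  fs$valid[2, 4:6] <- FALSE
  m <- sits_former(tiny_config(), seed = 1)
  p1 <- predict(m, fs)
  p2 <- predict(m, fs)
  expect_equal(dim(p1), c(6, 2))
  expect_lt(max(abs(rowSums(p1) - 1)), 1e-6)
  expect_identical(p1, p2)  # evaluation mode has no stochastic component
  fs_bad <- fs
  fs_bad$valid[1, ] <- FALSE
  expect_error(predict(m, fs_bad), "no valid timestep")
})

test_that("embeddings and gates have the contracted shapes and ranges", {
  fs <- make_feature_set(N = 4, T_ = 7, C = 5)
  m <- sits_former(tiny_config(C = 5), seed = 2)
  emb <- three_branch_embed(m, fs)
  expect_equal(dim(emb), c(4, 7, 16))
  w <- channel_attention_weights(m, fs)
  expect_equal(dim(w), c(4, 3 * m$config$branch_dim))
  expect_true(all(w > 0 & w < 1))
  g <- phenology_gates(m, fs)
  expect_equal(dim(g), c(4, 7, 16))
  expect_true(all(g > 0 & g < 1))
})

test_that("zero inputs give bias-only embeddings, identical across timesteps", {
  fs <- make_feature_set(N = 3, T_ = 6, C = 4)
  fs$X[] <- 0
  m <- sits_former(tiny_config(C = 4), seed = 3)
  emb <- three_branch_embed(m, fs)
  for (n in 1:3)
    for (t in 2:6)
      expect_equal(emb[n, t, ], emb[n, 1, ], tolerance = 1e-12)
  expect_equal(emb[1, 1, ], emb[3, 1, ], tolerance = 1e-12)
})

test_that("zeroed channel-attention weights give sigmoid(0) = 0.5", {
  fs <- make_feature_set(N = 3, T_ = 6, C = 4)
  m <- zero_param(sits_former(tiny_config(C = 4), seed = 4),
                  c("Ws1", "bs1", "Ws2", "bs2"))
  w <- channel_attention_weights(m, fs)
  expect_true(all(abs(w - 0.5) < 1e-12))
})

test_that("pairwise interaction branch enumerates channel products", {
  C <- 4
  fs <- make_feature_set(N = 1, T_ = 3, C = C)
  fs$X[] <- 0
  fs$X[1, , 2] <- c(1, 2, 3)   # single nonzero channel
  m <- sits_former(tiny_config(C = C), seed = 5)
  out <- ricesits:::model_intermediates(m, fs)
  pair <- out$branches$pair
  expect_equal(ncol(pair), C * (C + 1) / 2)
  # only the self-pair (2,2) is nonzero
  q <- 0; self22 <- NA
  for (i in 1:C) for (j in i:C) {
    q <- q + 1
    if (i == 2 && j == 2) self22 <- q
  }
  expect_equal(pair[, self22], c(1, 4, 9))
  expect_true(all(pair[, -self22] == 0))
})

test_that("positional encoding depends on day of year, not sequence index", {
  m <- sits_former(tiny_config(), seed = 6)
  a <- positional_encoding(m, c(160, 200, 240, 280))
  b <- positional_encoding(m, c(160, 180, 200, 220, 240, 260, 280))
  expect_equal(a[1, ], b[1, ], tolerance = 1e-12)  # same DOY, index 1 vs 1
  expect_equal(a[2, ], b[3, ], tolerance = 1e-12)  # DOY 200 at indices 2 vs 3
  expect_equal(a[4, ], b[7, ], tolerance = 1e-12)
  expect_equal(a[1, ], positional_encoding(m, c(160, 160))[2, ],
               tolerance = 1e-12)
  expect_error(positional_encoding(m, c(100, 400)), "DOY")
})

test_that("seasonal stage bins map transplanting / growth / ripening", {
  # zero the DOY projection so the encoding reduces to the stage embedding
  m <- zero_param(sits_former(tiny_config(), seed = 7), c("Wp", "bp"))
  pe <- positional_encoding(m, c(160, 165, 220, 250, 280, 300))
  expect_equal(pe[1, ], pe[2, ], tolerance = 1e-12)  # both transplanting
  expect_equal(pe[3, ], pe[4, ], tolerance = 1e-12)  # both growth
  expect_equal(pe[5, ], pe[6, ], tolerance = 1e-12)  # both ripening
  expect_gt(max(abs(pe[1, ] - pe[3, ])), 1e-4)
  expect_gt(max(abs(pe[3, ] - pe[5, ])), 1e-4)
})

test_that("zeroed gate weights halve the pooled representation", {
  fs <- make_feature_set(N = 4, T_ = 6, C = 3)
  gated <- zero_param(sits_former(tiny_config(gate_enabled = TRUE), seed = 8),
                      c("Wg1", "bg1", "Wg2", "bg2"))
  plain <- sits_former(tiny_config(gate_enabled = FALSE), seed = 8)
  # share every non-gate parameter between the two models
  lay_g <- ricesits:::cpp_param_layout(unclass(gated$config))
  keep <- !grepl("^Wg|^bg", lay_g$name)
  sizes <- lay_g$nrow * lay_g$ncol
  off <- cumsum(c(0, sizes))
  shared <- unlist(lapply(which(keep), function(i)
    gated$theta[(off[i] + 1):off[i + 1]]))
  plain$theta <- shared
  ig <- ricesits:::model_intermediates(gated, fs)
  ip <- ricesits:::model_intermediates(plain, fs)
  expect_equal(ig$pooled, ip$pooled / 2, tolerance = 1e-10)
  expect_true(all(abs(ig$gates - 0.5) < 1e-12))
})

test_that("masking a timestep is equivalent to deleting it", {
  T_ <- 10
  fs <- make_feature_set(N = 5, T_ = T_, C = 3, seed = 9)
  drop_t <- c(3, 8)
  fs_masked <- fs
  fs_masked$valid[, drop_t] <- FALSE
  keep <- setdiff(seq_len(T_), drop_t)
  fs_cut <- fs
  fs_cut$X <- fs$X[, keep, , drop = FALSE]
  fs_cut$valid <- fs$valid[, keep, drop = FALSE]
  fs_cut$doys <- fs$doys[keep]
  m <- sits_former(tiny_config(), seed = 10)
  expect_equal(predict(m, fs_masked), predict(m, fs_cut), tolerance = 1e-10)
})

test_that("spatio-spectral patch embedding is time-distributed", {
  P <- 3; Tn <- 5; N <- 2
  cfg <- tiny_config(use_patch_branch = TRUE, patch_size = P, n_bands = 2,
                     conv_filters = 4)
  m <- sits_former(cfg, seed = 11)
  set.seed(11)
  patches <- array(runif(N * P * P * 2 * Tn), c(N, P, P, 2, Tn))
  doys <- seq(160, by = 10, length.out = Tn)
  emb <- spatio_spectral_embed(m, patches, doys)
  expect_equal(dim(emb), c(N, Tn, 16))
  # permuting two timesteps permutes the embedding rows
  perm <- c(1, 4, 3, 2, 5)
  emb_p <- spatio_spectral_embed(m, patches[, , , , perm, drop = FALSE], doys)
  expect_equal(emb_p[, 2, ], emb[, 4, ], tolerance = 1e-12)
  expect_equal(emb_p[, 4, ], emb[, 2, ], tolerance = 1e-12)
  # zero patches embed identically at every timestep (bias pathway only)
  z <- spatio_spectral_embed(m, array(0, dim(patches)), doys)
  for (t in 2:Tn) expect_equal(z[1, t, ], z[1, 1, ], tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(12)
  N <- 4; T_ <- 6; C <- 4; P <- 3
  cfg <- tiny_config(C = C, dropout = 0, use_patch_branch = TRUE,
                     patch_size = P, n_bands = 2, conv_filters = 3)
  m <- sits_former(cfg, seed = 13)
  fs <- make_feature_set(N = N, T_ = T_, C = C, seed = 12)
  fs$valid[1, c(2, 5)] <- FALSE
  fs$label <- c(0L, 1L, 1L, 0L)
  patches <- array(runif(N * P * P * 2 * T_), c(N, P, P, 2, T_))
  lg <- ricesits:::model_loss_grads(m, fs, fs$label, patches = patches)
  expect_true(is.finite(lg$loss))
  idx <- sort(sample(length(m$theta), 120))
  eps <- 1e-5
  num <- vapply(idx, function(k) {
    mp <- m; mp$theta[k] <- mp$theta[k] + eps
    mm <- m; mm$theta[k] <- mm$theta[k] - eps
    (ricesits:::model_loss_grads(mp, fs, fs$label, patches)$loss -
       ricesits:::model_loss_grads(mm, fs, fs$label, patches)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - lg$grad[idx])), 1e-8)
})

test_that("architecture presets toggle the ablation variants", {
  orig <- architecture_preset("original", n_channels = 3)
  expect_false(orig$embed_multibranch)
  expect_false(orig$pos_adaptive)
  expect_false(orig$gate_enabled)
  full <- architecture_preset("full", n_channels = 3)
  expect_true(full$embed_multibranch && full$pos_adaptive && full$gate_enabled)
  ms <- architecture_preset("multiscale_embedding", n_channels = 3)
  expect_true(ms$embed_multibranch); expect_false(ms$gate_enabled)
  # each variant runs end to end
  fs <- make_feature_set(N = 3, T_ = 5, C = 3)
  for (p in c("original", "multiscale_embedding", "adaptive_encoding",
              "phenology_gate")) {
    cfg <- architecture_preset(p, n_channels = 3, d_model = 16, n_heads = 4,
                               n_layers = 1, d_ff = 24)
    pr <- predict(sits_former(cfg, seed = 1), fs)
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  }
})

test_that("parameter count is finite and reported", {
  m <- sits_former(sits_former_config(n_channels = 9), seed = 1)
  expect_gt(n_parameters(m), 1e5)
  expect_lt(n_parameters(m), 1e6)
  expect_output(print(m), "parameters")
})
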