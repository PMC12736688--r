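# shared fixtures: all data is generated in code, no files

# a small raw feature_set with controllable labels and validity
make_feature_set <- function(N = 8, T_ = 10, C = 3, seed = 1,
                             doys = seq(160, by = 8, length.out = T_)) {
  set.seed(seed)
  structure(list(X = array(stats::rnorm(N * T_ * C), c(N, T_, C)),
                 channels = paste0("ch", seq_len(C)),
                 doys = doys, valid = matrix(TRUE, N, T_),
                 label = rep_len(c(0L, 1L), N),
                 polygon_id = seq_len(N)),
            class = "feature_set")
}

# linearly separable features: channel 1 mean differs by class
make_separable_set <- function(N = 200, T_ = 8, C = 3, shift = 2, seed = 2) {
  fs <- make_feature_set(N, T_, C, seed = seed)
  y <- rep(0:1, each = N / 2)
  fs$X[y == 1, , 1] <- fs$X[y == 1, , 1] + shift
  fs$label <- y
  fs$polygon_id <- rep(seq_len(N / 2), each = 2)
  fs
}

# tiny architecture so forward/backward tests run in milliseconds
tiny_config <- function(C = 3, ...) {
  sits_former_config(n_channels = C, d_model = 16, n_heads = 4, n_layers = 2,
                     d_ff = 24, branch_dim = 6, branch_hidden = 5,
                     gate_hidden = 7, head_hidden = 8, ...)
}

# small labeled scene for pipeline-level tests
small_scene <- function(n_polygons = 60, seed = 5, gap_rate = 0.3, ...) {
  build_dataset(scene_config(n_polygons = n_polygons, points_per_polygon = 3,
                             gap_rate = gap_rate, seed = seed, ...))
}

# zero out a named parameter block of a model (uses the C++ layout)
zero_param <- function(model, names) {
  lay <- ricesits:::cpp_param_layout(unclass(model$config))
  off <- cumsum(c(0, lay$nrow * lay$ncol))
  for (nm in names) {
    i <- match(nm, lay$name)
    stopifnot(!is.na(i))
    model$theta[(off[i] + 1):off[i + 1]] <- 0
  }
  model
}
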