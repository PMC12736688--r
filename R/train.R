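# run an expression under a temporary RNG state
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Polygon-group-isolated train/test split
#'
#' Splits samples at polygon granularity: every sample of a polygon goes
#' exclusively to the training or to the test set, severing the spatial
#' correlation between splits that makes point-level splits overestimate
#' accuracy. Stratified by label at the polygon level, so the achieved test
#' fraction is within one polygon of the target per class.
#'
#' @param polygon_id Polygon identifier per sample.
#' @param label Binary label per sample (constant within polygon).
#' @param test_fraction Target test fraction of polygons (default 0.2).
#' @param seed Integer seed; the split is deterministic given it.
#' @param stratify Stratify polygon sampling by label (default TRUE).
#' @return A `split_assignment`: `train` and `test` sample indices,
#'   `test_polygons`, `seed`, `test_fraction`.
#' @export
group_split <- function(polygon_id, label, test_fraction = 0.2, seed = 1,
                        stratify = TRUE) {
  stopifnot(length(polygon_id) == length(label),
            test_fraction > 0, test_fraction < 1)
  first <- !duplicated(polygon_id)
  polys <- polygon_id[first]
  plab <- label[first]
  if (any(tapply(label, polygon_id, function(x) length(unique(x))) > 1))
    stop("a polygon carries more than one label; groups must be label-pure")
  test_polys <- with_local_seed(seed, {
    if (stratify) {
      unlist(lapply(unique(plab), function(lv) {
        p <- polys[plab == lv]
        if (length(p) < 2)
          stop("need at least 2 polygons per class to split (class ", lv, ")")
        sample(p, round(test_fraction * length(p)))
      }), use.names = FALSE)
    } else {
      if (length(polys) < 2) stop("need at least 2 polygons to split")
      sample(polys, round(test_fraction * length(polys)))
    }
  })
  is_test <- polygon_id %in% test_polys
  structure(list(train = which(!is_test), test = which(is_test),
                 test_polygons = test_polys, seed = seed,
                 test_fraction = test_fraction),
            class = "split_assignment")
}

#' Training configuration
#'
#' Optimization hyperparameters. Defaults follow the published training
#' strategy: AdamW at learning rate 0.001, cross-entropy loss, 100 epochs
#' with batch size 32, global gradient-norm clipping at 1.0, cosine
#' annealing (reduce-on-plateau available via `scheduler = "plateau"`).
#'
#' @param epochs,batch_size,lr Optimization basics.
#' @param weight_decay AdamW decoupled weight decay (applied to weight
#'   matrices, not biases or layer-norm parameters).
#' @param grad_clip_norm Global gradient-norm threshold.
#' @param scheduler `"cosine"` or `"plateau"`.
#' @param plateau_factor,plateau_patience Reduce-on-plateau parameters
#'   (validation loss monitored).
#' @param validation_fraction Fraction of training polygons held out for
#'   per-epoch validation metrics (0 disables; forced to 0.1 for the
#'   plateau scheduler when no validation set is given).
#' @param precision `"float"` (single precision, the training default on
#'   CPU) or `"double"`.
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, lr = 1e-3,
                         weight_decay = 0.01, grad_clip_norm = 1.0,
                         scheduler = c("cosine", "plateau"),
                         plateau_factor = 0.5, plateau_patience = 5,
                         validation_fraction = 0,
                         precision = c("float", "double"), seed = 1) {
  scheduler <- match.arg(scheduler)
  precision <- match.arg(precision)
  stopifnot(lr > 0, epochs >= 1, grad_clip_norm > 0, batch_size >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 grad_clip_norm = grad_clip_norm, scheduler = scheduler,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 validation_fraction = validation_fraction,
                 precision = precision, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the classifier
#'
#' Fits the standardizer on the training features only (stored in the model
#' and applied to any later input, so test statistics never leak into the
#' scaling), then optimizes the network with AdamW, gradient clipping and
#' the configured learning-rate schedule. Fully reproducible given the
#' seeds and single-threaded execution.
#'
#' @param model A `sits_former` (untrained or to be fine-tuned).
#' @param fs_train Training `feature_set` (raw, unstandardized).
#' @param tconfig A [train_config()].
#' @param fs_val Optional validation `feature_set`; if absent and the
#'   configuration needs one, a polygon-level slice of the training set is
#'   held out.
#' @param patches_train,patches_val Optional patch arrays when the patch
#'   branch is enabled.
#' @return The trained `sits_former` with `history` (per-epoch loss,
#'   accuracy, learning rate, clip count) attached.
#' @export
train_sits_former <- function(model, fs_train, tconfig = train_config(),
                              fs_val = NULL, patches_train = NULL,
                              patches_val = NULL) {
  stopifnot(inherits(model, "sits_former"), inherits(fs_train, "feature_set"))
  if (dim(fs_train$X)[3] != model$config$n_channels)
    stop("feature channels (", dim(fs_train$X)[3],
         ") do not match the model configuration (",
         model$config$n_channels, ")")
  vfrac <- tconfig$validation_fraction
  if (tconfig$scheduler == "plateau" && is.null(fs_val) && vfrac == 0)
    vfrac <- 0.1
  if (is.null(fs_val) && vfrac > 0) {
    sp <- group_split(fs_train$polygon_id, fs_train$label,
                      test_fraction = vfrac, seed = tconfig$seed)
    fs_val <- subset_features(fs_train, sp$test)
    if (!is.null(patches_train)) {
      patches_val <- patches_train[sp$test, , , , , drop = FALSE]
      patches_train <- patches_train[sp$train, , , , , drop = FALSE]
    }
    fs_train <- subset_features(fs_train, sp$train)
  }

  std <- fit_standardizer(fs_train)
  fs_train_s <- apply_standardizer(fs_train, std)
  inp <- model_inputs(fs_train_s, patches_train)
  val <- list()
  if (!is.null(fs_val)) {
    fs_val_s <- apply_standardizer(fs_val, std)
    vinp <- model_inputs(fs_val_s, patches_val)
    val <- list(X = vinp$X, M = vinp$M, D = vinp$D,
                y = as.integer(fs_val_s$label))
    if (!is.null(vinp$P)) val$P <- vinp$P
  }

  res <- cpp_train(model$theta, unclass(model$config), inp$X, inp$M, inp$D,
                   inp$P, as.integer(fs_train_s$label), val,
                   unclass(tconfig), tconfig$seed)
  if (isTRUE(res$diverged))
    stop("training diverged (non-finite loss); last learning rate ",
         utils::tail(res$history$lr, 1),
         " after ", length(res$history$loss), " completed epochs")
  model$theta <- res$theta
  model$standardizer <- std
  model$trained <- TRUE
  model$history <- c(res$history, list(clip_count = res$clip_count,
                                       train_config = tconfig))
  model
}

#' Temporal-mean logistic baseline
#'
#' A deliberately simple comparison classifier for paired McNemar tests:
#' each sample is reduced to its per-channel mean over valid timesteps and
#' classified by logistic regression. It sees the temporal aggregate but
#' none of the trajectory shape, which is exactly the information the
#' transformer exploits.
#'
#' @param fs_train,fs_test Raw `feature_set`s.
#' @return `list(prob, class, fit)` for the test set.
#' @export
temporal_mean_logistic <- function(fs_train, fs_test) {
  pool <- function(fs) {
    N <- dim(fs$X)[1]; C <- dim(fs$X)[3]
    out <- matrix(0, N, C)
    for (n in seq_len(N)) {
      v <- fs$valid[n, ]
      out[n, ] <- colMeans(fs$X[n, v, , drop = FALSE][1, , , drop = TRUE],
                           na.rm = TRUE)
    }
    colnames(out) <- fs$channels
    out
  }
  tr <- as.data.frame(pool(fs_train)); tr$y <- fs_train$label
  te <- as.data.frame(pool(fs_test))
  fit <- stats::glm(y ~ ., data = tr, family = stats::binomial())
  p <- stats::predict(fit, newdata = te, type = "response")
  list(prob = as.numeric(p), class = as.integer(p >= 0.5), fit = fit)
}

#' Save / load a model checkpoint
#'
#' A versioned archive holding the architecture configuration, weights,
#' fitted standardizer, feature preset and training history. Forward
#' outputs are bit-identical after a save/load round trip.
#'
#' @param model A `sits_former`.
#' @param path Checkpoint path (RDS).
#' @return The path (save) or the restored `sits_former` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sits_former"))
  saveRDS(list(format = "ricesits-checkpoint", version = 1L,
               config = model$config, theta = model$theta,
               standardizer = model$standardizer,
               feature_preset = model$feature_preset,
               history = model$history, trained = model$trained,
               init_seed = model$init_seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ricesits-checkpoint"))
    stop("not a ricesits checkpoint: ", path)
  structure(list(config = x$config, theta = x$theta, trained = x$trained,
                 standardizer = x$standardizer,
                 feature_preset = x$feature_preset, history = x$history,
                 init_seed = x$init_seed),
            class = "sits_former")
}
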