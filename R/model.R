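#' Configuration of the enhanced SITS-Former classifier
#'
#' Architecture hyperparameters of the time-series transformer. The defaults
#' follow the published setup: model dimension 64, 4 encoder layers with 8
#' attention heads, feed-forward dimension 256, dropout 0.1 throughout,
#' GELU activations, global average pooling and a two-layer MLP head.
#'
#' The enhancement toggles reproduce the architecture-ablation variants:
#' `embed_multibranch` switches between the parallel three-branch feature
#' embedding with channel attention and a plain affine input projection;
#' `pos_adaptive` switches between the adaptive positional encoding
#' (learnable phenological-stage embedding plus a learnable projection of
#' sinusoidal day-of-year features) and the fixed sinusoidal encoding;
#' `gate_enabled` switches the phenology attention gate on or off;
#' `use_patch_branch` adds the 3D-convolutional spatio-spectral patch
#' embedding (two conv layers, 64 filters, stride 1, same padding).
#'
#' @param n_channels Number of input feature channels (see
#'   [feature_channels()]).
#' @param d_model Token dimension. Must be divisible by `n_heads`.
#' @param n_heads,n_layers,d_ff Encoder geometry.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param branch_dim,branch_hidden Width of each embedding branch and of the
#'   deep branch's hidden layer.
#' @param ca_reduction Channel-attention bottleneck reduction ratio.
#' @param gate_hidden,head_hidden Hidden widths of the gate MLP and the
#'   classification head.
#' @param n_classes Number of classes (2: rice / non-rice).
#' @param stage_breaks Day-of-year edges of the transplanting / growth /
#'   ripening bins used by the seasonal-stage embedding.
#' @param embed_multibranch,pos_adaptive,gate_enabled,use_patch_branch
#'   Enhancement toggles, see Details.
#' @param patch_size,n_bands,conv_filters Patch-branch geometry.
#' @return A `sits_former_config`.
#' @export
sits_former_config <- function(n_channels, d_model = 64, n_heads = 8,
                               n_layers = 4, d_ff = 256, dropout = 0.1,
                               branch_dim = 32, branch_hidden = 32,
                               ca_reduction = 4, gate_hidden = 32,
                               head_hidden = 32, n_classes = 2,
                               stage_breaks = c(172, 258),
                               embed_multibranch = TRUE,
                               pos_adaptive = TRUE, gate_enabled = TRUE,
                               use_patch_branch = FALSE, patch_size = 5,
                               n_bands = 4, conv_filters = 64) {
  stopifnot(d_model %% n_heads == 0, dropout >= 0, dropout < 1,
            patch_size %% 2 == 1, length(stage_breaks) == 2,
            n_channels >= 1)
  structure(list(n_channels = as.integer(n_channels),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 dropout = dropout, branch_dim = as.integer(branch_dim),
                 branch_hidden = as.integer(branch_hidden),
                 ca_reduction = as.integer(ca_reduction),
                 gate_hidden = as.integer(gate_hidden),
                 head_hidden = as.integer(head_hidden),
                 n_classes = as.integer(n_classes),
                 stage_breaks = as.numeric(stage_breaks),
                 embed_multibranch = isTRUE(embed_multibranch),
                 pos_adaptive = isTRUE(pos_adaptive),
                 gate_enabled = isTRUE(gate_enabled),
                 use_patch_branch = isTRUE(use_patch_branch),
                 patch_size = as.integer(patch_size),
                 n_bands = as.integer(n_bands),
                 conv_filters = as.integer(conv_filters)),
            class = "sits_former_config")
}

#' Architecture ablation presets
#'
#' Named variants matching the architecture-ablation rows: `"original"`
#' (affine embedding, fixed sinusoidal encoding, no gate), single-module
#' variants `"multiscale_embedding"`, `"adaptive_encoding"`,
#' `"phenology_gate"`, and `"full"` (all enhancements).
#'
#' @param preset Variant name.
#' @param n_channels Input channels.
#' @param ... Further arguments passed to [sits_former_config()].
#' @return A `sits_former_config`.
#' @export
architecture_preset <- function(preset = c("full", "original",
                                           "multiscale_embedding",
                                           "adaptive_encoding",
                                           "phenology_gate"),
                                n_channels, ...) {
  preset <- match.arg(preset)
  sw <- switch(preset,
    original = list(embed_multibranch = FALSE, pos_adaptive = FALSE,
                    gate_enabled = FALSE),
    multiscale_embedding = list(embed_multibranch = TRUE,
                                pos_adaptive = FALSE, gate_enabled = FALSE),
    adaptive_encoding = list(embed_multibranch = FALSE, pos_adaptive = TRUE,
                             gate_enabled = FALSE),
    phenology_gate = list(embed_multibranch = FALSE, pos_adaptive = FALSE,
                          gate_enabled = TRUE),
    full = list(embed_multibranch = TRUE, pos_adaptive = TRUE,
                gate_enabled = TRUE))
  do.call(sits_former_config, c(list(n_channels = n_channels), sw, list(...)))
}

#' Initialize a SITS-Former model
#'
#' Creates the model object with Xavier-uniform weight initialization
#' (biases zero, layer-norm gains one), deterministically from `seed`.
#'
#' @param config A [sits_former_config()].
#' @param seed Integer seed for the initialization.
#' @return A `sits_former` model object.
#' @export
sits_former <- function(config, seed = 1) {
  stopifnot(inherits(config, "sits_former_config"))
  theta <- cpp_init_params(unclass(config), as.integer(seed))
  structure(list(config = config, theta = theta, trained = FALSE,
                 standardizer = NULL, feature_preset = NULL,
                 history = NULL, init_seed = as.integer(seed)),
            class = "sits_former")
}

#' @export
print.sits_former <- function(x, ...) {
  cat("sits_former:", format(n_parameters(x), big.mark = ","),
      "parameters | d_model", x$config$d_model, "| layers",
      x$config$n_layers, "x", x$config$n_heads, "heads\n")
  cat("  multibranch:", x$config$embed_multibranch,
      "| adaptive pos:", x$config$pos_adaptive,
      "| gate:", x$config$gate_enabled,
      "| patch branch:", x$config$use_patch_branch, "\n")
  cat("  trained:", x$trained, "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `sits_former`.
#' @return Integer count.
#' @export
n_parameters <- function(model) length(model$theta)

# ---- tensor plumbing -------------------------------------------------------

# (N, T, C) array -> (N*T, C) matrix with each sample's T rows contiguous
flatten_tokens <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 1, 3)), d[1] * d[2], d[3])
}

# (N, P, P, B, T) patch array -> (N*T, P*P*B) row-per-token matrix
flatten_patches <- function(patches) {
  d <- dim(patches)
  ap <- aperm(patches, c(2, 3, 4, 5, 1))
  t(matrix(ap, d[2] * d[3] * d[4], d[5] * d[1]))
}

# assemble the C++ inputs from a feature_set (plus optional patches)
model_inputs <- function(fs, patches = NULL) {
  N <- dim(fs$X)[1]; T_ <- dim(fs$X)[2]
  list(X = flatten_tokens(fs$X),
       M = matrix(as.numeric(fs$valid), N, T_),
       D = matrix(rep(fs$doys, each = N), N, T_),
       P = if (!is.null(patches)) flatten_patches(patches))
}

subset_features <- function(fs, idx) {
  fs$X <- fs$X[idx, , , drop = FALSE]
  fs$valid <- fs$valid[idx, , drop = FALSE]
  fs$label <- fs$label[idx]
  fs$polygon_id <- fs$polygon_id[idx]
  if (!is.null(fs$class)) fs$class <- fs$class[idx]
  fs
}

#' Predict class probabilities
#'
#' Runs the forward pass in evaluation mode (deterministic, dropout off).
#' If the model carries a fitted standardizer (after training) it is applied
#' to the features first, so raw feature sets can be passed directly.
#'
#' @param object A `sits_former`.
#' @param fs A `feature_set` (see [featurize_scene()]).
#' @param type `"prob"` for an N x 2 probability matrix (columns non-rice,
#'   rice), `"class"` for 0/1 labels at the 0.5 rice-probability threshold.
#' @param patches Optional patch array (N x P x P x bands x T) when the
#'   patch branch is enabled.
#' @param batch_size Forward-pass batch size (memory control).
#' @param standardize Apply the stored standardizer (default TRUE).
#' @param ... Unused.
#' @return Probability matrix or integer class vector.
#' @export
predict.sits_former <- function(object, fs, type = c("prob", "class"),
                                patches = NULL, batch_size = 256,
                                standardize = TRUE, ...) {
  type <- match.arg(type)
  if (standardize && !is.null(object$standardizer))
    fs <- apply_standardizer(fs, object$standardizer)
  N <- dim(fs$X)[1]
  probs <- matrix(0, N, object$config$n_classes)
  for (s0 in seq(1, N, by = batch_size)) {
    idx <- s0:min(N, s0 + batch_size - 1)
    inp <- model_inputs(subset_features(fs, idx),
                        patches = if (!is.null(patches))
                          patches[idx, , , , , drop = FALSE])
    out <- cpp_forward(object$theta, unclass(object$config), inp$X, inp$M,
                       inp$D, inp$P, FALSE)
    probs[idx, ] <- out$probs
  }
  if (type == "prob") probs else as.integer(probs[, 2] >= 0.5)
}

# forward pass returning internal activations (used by the module-level
# accessors and their tests); always evaluation mode, double precision
model_intermediates <- function(model, fs, patches = NULL) {
  inp <- model_inputs(fs, patches)
  cpp_forward(model$theta, unclass(model$config), inp$X, inp$M, inp$D,
              inp$P, TRUE)
}

reshape_tokens <- function(m, N, T_) {
  aperm(array(m, dim = c(T_, N, ncol(m))), c(2, 1, 3))
}

#' Three-branch feature embedding
#'
#' Returns the fused token embeddings produced by the parallel three-branch
#' embedding (affine projection, two-layer MLP, pairwise feature
#' interactions) after channel attention, one `d_model` vector per
#' timestep.
#'
#' @param model A `sits_former` with `embed_multibranch = TRUE`.
#' @param fs A `feature_set`.
#' @return N x T x d_model array.
#' @export
three_branch_embed <- function(model, fs) {
  if (!model$config$embed_multibranch)
    stop("model was configured with the plain affine embedding")
  out <- model_intermediates(model, fs)
  reshape_tokens(out$embed, dim(fs$X)[1], dim(fs$X)[2])
}

#' Channel-attention weights
#'
#' Sigmoid recalibration weights (one per concatenated branch channel and
#' sample) produced by the squeeze-and-excitation step of the embedding.
#'
#' @inheritParams three_branch_embed
#' @return N x (3 * branch_dim) matrix of weights in (0, 1).
#' @export
channel_attention_weights <- function(model, fs) {
  if (!model$config$embed_multibranch)
    stop("channel attention exists only with the multibranch embedding")
  model_intermediates(model, fs)$ca_weights
}

#' Positional encodings for a day-of-year sequence
#'
#' The additive encoding of each observation date: with
#' `pos_adaptive = TRUE` the sum of the learnable phenological-stage
#' embedding (transplanting / growth / ripening bins) and a learnable affine
#' map of sinusoidal DOY features; otherwise the fixed sinusoid. The
#' encoding depends only on the DOY, not on the position index, which is
#' what makes irregular sampling well-posed.
#'
#' @param model A `sits_former`.
#' @param doys Integer days of year in `[1, 366]`.
#' @return length(doys) x d_model matrix.
#' @export
positional_encoding <- function(model, doys) {
  T_ <- length(doys)
  C <- model$config$n_channels
  fs <- structure(list(X = array(0, dim = c(1, T_, C)),
                       channels = rep("x", C), doys = doys,
                       valid = matrix(TRUE, 1, T_), label = 0L,
                       polygon_id = 1L),
                  class = "feature_set")
  model_intermediates(model, fs)$pos
}

#' Phenology-gate activations
#'
#' Per-timestep, per-dimension sigmoid gates applied to the encoder
#' outputs, conditioned on the token and its positional (phenological)
#' context.
#'
#' @inheritParams three_branch_embed
#' @return N x T x d_model array of gates in (0, 1).
#' @export
phenology_gates <- function(model, fs) {
  if (!model$config$gate_enabled)
    stop("the phenology gate is disabled in this configuration")
  out <- model_intermediates(model, fs)
  reshape_tokens(out$gates, dim(fs$X)[1], dim(fs$X)[2])
}

#' Spatio-spectral patch embedding
#'
#' Per-timestep embedding of the P x P x bands neighborhood through two 3D
#' convolutional layers (stride 1, same padding), flattening and a fully
#' connected projection to `d_model` -- the patch pathway of the original
#' architecture, applied time-distributed.
#'
#' @param model A `sits_former` with `use_patch_branch = TRUE`.
#' @param patches N x P x P x bands x T array.
#' @param doys Shared day-of-year grid (length T).
#' @return N x T x d_model array.
#' @export
spatio_spectral_embed <- function(model, patches, doys) {
  if (!model$config$use_patch_branch)
    stop("patch branch is disabled in this configuration")
  d <- dim(patches)
  if (d[2] != model$config$patch_size || d[4] != model$config$n_bands)
    stop("patch dimensions do not match the model configuration")
  N <- d[1]; T_ <- d[5]
  C <- model$config$n_channels
  fs <- structure(list(X = array(0, dim = c(N, T_, C)),
                       channels = rep("x", C), doys = doys,
                       valid = matrix(TRUE, N, T_), label = rep(0L, N),
                       polygon_id = seq_len(N)),
                  class = "feature_set")
  out <- model_intermediates(model, fs, patches = patches)
  reshape_tokens(out$patch_embed, N, T_)
}

# loss and flat gradient at given parameters (double precision); the
# gradient-check tests diff this against finite differences
model_loss_grads <- function(model, fs, labels, patches = NULL) {
  inp <- model_inputs(fs, patches)
  cpp_loss_grads(model$theta, unclass(model$config), inp$X, inp$M, inp$D,
                 inp$P, as.integer(labels))
}
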