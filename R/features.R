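#' Feature presets
#'
#' Channel compositions used by the classifier and its feature-ablation
#' variants:
#' \describe{
#'   \item{`baseline`}{NDVI, LSWI, EVI at each valid step (3 channels).}
#'   \item{`+tdvi`}{baseline plus the temporal difference of each index
#'     (6 channels).}
#'   \item{`+ncrvi`}{baseline plus the normalized change rate of each index
#'     (6 channels).}
#'   \item{`complete`}{all five families: the three indices, their TDVI and
#'     their NCRVI (9 channels).}
#'   \item{`ndvi_deriv`}{the three indices plus TDVI and NCRVI of NDVI only
#'     (5 channels).}
#' }
#'
#' @param preset Preset name.
#' @return Character vector of channel names.
#' @export
feature_channels <- function(preset = c("complete", "baseline", "+tdvi",
                                        "+ncrvi", "ndvi_deriv")) {
  preset <- match.arg(preset)
  base <- c("ndvi", "lswi", "evi")
  switch(preset,
         baseline = base,
         "+tdvi" = c(base, paste0("tdvi_", base)),
         "+ncrvi" = c(base, paste0("ncrvi_", base)),
         complete = c(base, paste0("tdvi_", base), paste0("ncrvi_", base)),
         ndvi_deriv = c(base, "tdvi_ndvi", "ncrvi_ndvi"))
}

# derivative channels between consecutive valid steps of one series;
# the first valid step is 0 by convention (padding-neutral after
# standardization), invalid steps emit 0 (never NaN).
deriv_channels <- function(values, valid, ncrvi_guard = 1e-6) {
  iv <- which(valid)
  td <- nc <- rep(0, length(values))
  if (length(iv) >= 2) {
    prev <- values[iv[-length(iv)]]
    cur <- values[iv[-1]]
    td[iv[-1]] <- cur - prev
    nc[iv[-1]] <- ifelse(abs(prev) < ncrvi_guard, 0, (cur - prev) / prev * 100)
  }
  list(tdvi = td, ncrvi = nc)
}

#' Assemble a per-sample phenological feature sequence
#'
#' Builds the T x C feature matrix of one sample from its reconstructed
#' index series. Derivative channels (TDVI, NCRVI) are computed between
#' consecutive valid steps only; the first valid step gets 0. `delta_t`
#' (day gaps to the previous valid step) is carried as metadata and not
#' used to normalize TDVI, which is a plain difference.
#'
#' @param indices Named list with numeric vectors `ndvi`, `lswi`, `evi`.
#' @param doys Days of year, same length.
#' @param valid Logical validity mask.
#' @param preset Feature preset, see [feature_channels()].
#' @return A `feature_sequence`: `features` (T x C), `channels`, `doys`,
#'   `valid`, `delta_t`.
#' @export
assemble_features <- function(indices, doys,
                              valid = rep(TRUE, length(doys)),
                              preset = "complete") {
  channels <- feature_channels(preset)
  stopifnot(all(c("ndvi", "lswi", "evi") %in% names(indices)))
  T_ <- length(doys)
  lens <- vapply(indices[c("ndvi", "lswi", "evi")], length, numeric(1))
  if (any(lens != T_)) stop("all index series must share the doy grid")
  cols <- list(ndvi = indices$ndvi, lswi = indices$lswi, evi = indices$evi)
  need_deriv <- grepl("^(tdvi|ncrvi)_", channels)
  for (ch in channels[need_deriv]) {
    parts <- strsplit(ch, "_")[[1]]
    d <- deriv_channels(indices[[parts[2]]], valid)
    cols[[ch]] <- d[[parts[1]]]
  }
  X <- do.call(cbind, cols[channels])
  X[!valid, ] <- 0
  iv <- which(valid)
  dt <- rep(0, T_)
  if (length(iv) >= 2) dt[iv[-1]] <- diff(doys[iv])
  structure(list(features = unname(X), channels = channels, doys = doys,
                 valid = valid, delta_t = dt),
            class = "feature_sequence")
}

#' Featurize a reconstructed scene
#'
#' Vectorized feature assembly for all samples of a [reconstruct_scene()]
#' result. With the default `mask_policy = "filled"` the reconstructed
#' series is treated as continuous (every step valid, as the gap-filled
#' trajectories are what the classifier consumes); with `"observed"` the
#' original cloud mask is kept and derivative channels skip masked steps.
#'
#' @param recon A `recon_series` from [reconstruct_scene()].
#' @param preset Feature preset, see [feature_channels()].
#' @param mask_policy `"filled"` or `"observed"`.
#' @return A `feature_set`: `X` (N x T x C array), `channels`, `doys`,
#'   `valid` (N x T), `label`, `polygon_id`, `class`.
#' @export
featurize_scene <- function(recon, preset = "complete",
                            mask_policy = c("filled", "observed")) {
  mask_policy <- match.arg(mask_policy)
  channels <- feature_channels(preset)
  N <- nrow(recon$index$ndvi); T_ <- ncol(recon$index$ndvi)
  X <- array(0, dim = c(N, T_, length(channels)),
             dimnames = list(NULL, NULL, channels))
  if (mask_policy == "filled") {
    validm <- matrix(TRUE, N, T_)
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      if (!grepl("^(tdvi|ncrvi)_", ch)) {
        X[, , ci] <- recon$index[[ch]]
      } else {
        parts <- strsplit(ch, "_")[[1]]
        V <- recon$index[[parts[2]]]
        D <- cbind(0, t(diff(t(V))))
        if (parts[1] == "tdvi") {
          X[, , ci] <- D
        } else {
          prev <- cbind(0, V[, -T_, drop = FALSE])
          R <- ifelse(abs(prev) < 1e-6, 0, D / prev * 100)
          R[, 1] <- 0
          X[, , ci] <- R
        }
      }
    }
  } else {
    validm <- recon$valid
    for (n in seq_len(N)) {
      fs <- assemble_features(lapply(recon$index, function(m) m[n, ]),
                              recon$doys, valid = validm[n, ],
                              preset = preset)
      X[n, , ] <- fs$features
    }
  }
  structure(list(X = X, channels = channels, doys = recon$doys,
                 valid = validm, label = recon$label,
                 polygon_id = recon$polygon_id, class = recon$class),
            class = "feature_set")
}

#' Per-channel standardization
#'
#' `fit_standardizer()` learns per-channel mean and standard deviation over
#' the valid steps of a (training) feature set; `apply_standardizer()`
#' applies stored statistics unchanged, so test data is scaled with the
#' training parameters and never leaks into them. Standard deviations are
#' floored at 1e-8 (constant channels standardize to 0).
#'
#' @param fs A `feature_set` from [featurize_scene()].
#' @return `fit_standardizer`: a `standardizer` with `mean`, `sd`,
#'   `channels`; `apply_standardizer`: the feature set with standardized
#'   `X`.
#' @export
fit_standardizer <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  C <- dim(fs$X)[3]
  vmask <- as.vector(fs$valid)
  m <- s <- numeric(C)
  for (c_ in seq_len(C)) {
    v <- as.vector(fs$X[, , c_])[vmask]
    m[c_] <- mean(v)
    s[c_] <- stats::sd(v)
  }
  structure(list(mean = m, sd = pmax(s, 1e-8), channels = fs$channels),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @export
apply_standardizer <- function(fs, std) {
  if (!inherits(std, "standardizer")) stop("standardizer has not been fitted")
  if (!identical(std$channels, fs$channels))
    stop("standardizer channels do not match the feature set")
  for (c_ in seq_along(std$channels))
    fs$X[, , c_] <- (fs$X[, , c_] - std$mean[c_]) / std$sd[c_]
  fs
}

#' Save / load a standardizer as JSON
#' @param std A `standardizer`.
#' @param path JSON path.
#' @return The path (write) or the `standardizer` (read).
#' @export
write_standardizer <- function(std, path) {
  jsonlite::write_json(unclass(std), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                 channels = as.character(x$channels)),
            class = "standardizer")
}
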