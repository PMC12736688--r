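#' Default scene-classification codes treated as invalid
#'
#' Cloud shadow (3), water (6), medium- and high-probability cloud (8, 9),
#' cirrus (10) and snow (11), following the Sentinel-2 scene classification
#' layer convention. Configurable wherever a `mask_set` argument appears.
#'
#' @return Integer vector of codes.
#' @export
default_mask_codes <- function() c(3L, 6L, 8L, 9L, 10L, 11L)

#' A masked time series
#'
#' Bundles observation values with their days of year and a validity mask;
#' invalid slots are treated as missing by the reconstruction operations.
#'
#' @param values Numeric observations.
#' @param doys Days of year, same length, strictly increasing.
#' @param valid Logical mask; at least one entry must be `TRUE`.
#' @return A `masked_series` list.
#' @export
masked_series <- function(values, doys, valid = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(doys), length(values) == length(valid),
            !is.unsorted(doys, strictly = TRUE))
  if (!any(valid)) stop("masked_series needs at least one valid observation")
  structure(list(values = as.numeric(values), doys = as.numeric(doys),
                 valid = as.logical(valid)),
            class = "masked_series")
}

#' Apply quality codes to a series
#'
#' Marks observations invalid exactly where their quality code is in
#' `mask_set`; values are untouched. An empty mask set is the identity.
#'
#' @param values,doys Observations and their days of year.
#' @param quality Integer quality codes aligned with `values`.
#' @param mask_set Codes to mask (default [default_mask_codes()]).
#' @return A [masked_series()].
#' @export
apply_quality_mask <- function(values, doys, quality,
                               mask_set = default_mask_codes()) {
  if (length(quality) != length(values))
    stop("quality codes and values have different lengths")
  masked_series(values, doys, valid = !(quality %in% mask_set))
}

# Savitzky-Golay weights for one target point on an arbitrary (irregular)
# coordinate grid: the row of the local polynomial projection that yields
# the fitted value at the target. `dt` are coordinate offsets to the target.
sg_point_weights <- function(dt, polyorder) {
  X <- outer(dt, 0:polyorder, `^`)
  # fitted value at offset 0 is the intercept of the local fit
  XtX <- crossprod(X)
  drop(solve(XtX, t(X))[1, ])
}

#' Savitzky-Golay smoothing on an irregular day-of-year grid
#'
#' Local least-squares polynomial smoothing of the valid subsequence: for
#' each valid observation a degree-`polyorder` polynomial is fitted over the
#' `window` nearest valid observations (in sequence order; at the series
#' boundaries the window is shifted, not shrunk, as in the classical filter)
#' and evaluated at that observation's day of year. Fitting in day-of-year
#' coordinates rather than sample index makes the filter exact for
#' polynomials of degree `<= polyorder` even when cloud masking leaves
#' irregular gaps.
#'
#' If fewer than `window` observations are valid the series is returned
#' unchanged with a warning.
#'
#' @param series A [masked_series()].
#' @param window Odd window length in observations (default 7).
#' @param polyorder Polynomial degree, `< window` (default 2).
#' @return A `masked_series` with smoothed values at valid slots.
#' @export
sg_smooth <- function(series, window = 7, polyorder = 2) {
  stopifnot(inherits(series, "masked_series"),
            window %% 2 == 1, polyorder < window)
  iv <- which(series$valid)
  n <- length(iv)
  if (n < window) {
    warning("fewer valid observations (", n, ") than the smoothing window (",
            window, "); series returned unsmoothed")
    return(series)
  }
  t <- series$doys[iv]
  y <- series$values[iv]
  h <- (window - 1) / 2
  out <- y
  for (i in seq_len(n)) {
    lo <- min(max(i - h, 1), n - window + 1)
    j <- lo:(lo + window - 1)
    w <- sg_point_weights(t[j] - t[i], polyorder)
    out[i] <- sum(w * y[j])
  }
  res <- series
  res$values[iv] <- out
  res
}

#' Harmonic regression fit
#'
#' Ordinary least squares of the valid observations on the Fourier basis
#' `{1, cos(2 pi k t / period), sin(2 pi k t / period)}`, `k = 1..K`. Used
#' to estimate vegetation-index values at cloud-obscured dates: the fitted
#' curve captures the single green-up/senescence cycle of the season (K = 2
#' adds the asymmetry between the two).
#'
#' @param series A [masked_series()].
#' @param K Number of harmonics (default 2).
#' @param period Period in days (default 365).
#' @param label Sample label used in error messages.
#' @return A `harmonic_fit`: `a0`, vectors `a`, `b` of cosine/sine
#'   coefficients, `K`, `period`.
#' @export
harmonic_fit <- function(series, K = 2, period = 365, label = "series") {
  stopifnot(inherits(series, "masked_series"), K >= 1)
  iv <- which(series$valid)
  p <- 2 * K + 1
  if (length(iv) < p)
    stop("harmonic reconstruction failed for ", label, ": ", length(iv),
         " valid observations but ", p, " coefficients")
  X <- harmonic_design(series$doys[iv], K, period)
  qx <- qr(X)
  if (qx$rank < p)
    stop("harmonic reconstruction failed for ", label,
         ": rank-deficient design (duplicate or degenerate days of year)")
  beta <- qr.coef(qx, series$values[iv])
  structure(list(a0 = beta[1], a = beta[1 + seq_len(K)],
                 b = beta[1 + K + seq_len(K)], K = K, period = period),
            class = "harmonic_fit")
}

harmonic_design <- function(t, K, period) {
  w <- 2 * pi * outer(t, seq_len(K)) / period
  cbind(1, cos(w), sin(w))
}

#' Evaluate a harmonic fit at arbitrary days of year
#' @param object A `harmonic_fit`.
#' @param doys Days of year.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.harmonic_fit <- function(object, doys, ...) {
  drop(harmonic_design(doys, object$K, object$period) %*%
         c(object$a0, object$a, object$b))
}

#' Harmonic gap filling
#'
#' Fits [harmonic_fit()] on the valid observations and replaces the invalid
#' slots with the fitted curve. Valid observations are never altered (fill
#' gaps only): the smoothed observations themselves are the best available
#' data, the harmonic model only interpolates where clouds removed them.
#'
#' @inheritParams harmonic_fit
#' @return `list(fit =, series =)`: the fit and the gap-filled
#'   `masked_series` (all slots valid in the `filled` element, original
#'   mask kept in `valid`).
#' @export
harmonic_fit_fill <- function(series, K = 2, period = 365, label = "series") {
  fit <- harmonic_fit(series, K = K, period = period, label = label)
  filled <- series$values
  gaps <- !series$valid
  if (any(gaps)) filled[gaps] <- predict(fit, series$doys[gaps])
  list(fit = fit, series = series, filled = filled)
}

#' Reconstruct gap-free vegetation-index series for a whole scene
#'
#' The full preprocessing chain of the pipeline, per sample and per index
#' (NDVI, LSWI, EVI): quality masking, Savitzky-Golay smoothing of the
#' valid subsequence, harmonic-regression estimation of the cloud-obscured
#' values. Valid (smoothed) observations are preserved; only gaps receive
#' fitted values.
#'
#' @param scene A `rice_scene` (see [build_dataset()] / [read_scene_csv()]).
#' @param mask_set Quality codes treated as missing.
#' @param sg_window,sg_order Savitzky-Golay window/degree.
#' @param K,period Harmonic regression order and period (days).
#' @return A `recon_series` object: `index` (list of N x T matrices `ndvi`,
#'   `lswi`, `evi`), `doys`, `valid` (N x T logical, the post-mask validity),
#'   `fill_fraction` (per sample), plus `label`, `class`, `polygon_id`
#'   carried over.
#' @export
reconstruct_scene <- function(scene, mask_set = default_mask_codes(),
                              sg_window = 7, sg_order = 2,
                              K = 2, period = 365) {
  N <- dim(scene$bands)[1]; T_ <- dim(scene$bands)[2]
  doys <- scene$doys
  nd <- ndvi(scene$bands[, , "B8"], scene$bands[, , "B4"])
  lw <- lswi(scene$bands[, , "B8"], scene$bands[, , "B11"])
  ev <- evi(scene$bands[, , "B8"], scene$bands[, , "B4"],
            scene$bands[, , "B2"])
  raw <- list(ndvi = matrix(nd, N, T_), lswi = matrix(lw, N, T_),
              evi = matrix(ev, N, T_))
  validm <- matrix(!(scene$quality %in% mask_set), N, T_)
  out <- lapply(raw, function(m) m)
  h <- (sg_window - 1) / 2
  p <- 2 * K + 1
  for (n in seq_len(N)) {
    iv <- which(validm[n, ])
    nv <- length(iv)
    if (nv < p)
      stop("harmonic reconstruction failed for sample ", n, ": ", nv,
           " valid observations but ", p, " coefficients")
    tv <- doys[iv]
    Y <- cbind(raw$ndvi[n, iv], raw$lswi[n, iv], raw$evi[n, iv])
    # SG smoothing, one weight vector per point, shared across indices
    if (nv >= sg_window) {
      S <- Y
      for (i in seq_len(nv)) {
        lo <- min(max(i - h, 1), nv - sg_window + 1)
        j <- lo:(lo + sg_window - 1)
        w <- sg_point_weights(tv[j] - tv[i], sg_order)
        S[i, ] <- w %*% Y[j, , drop = FALSE]
      }
      Y <- S
    }
    # harmonic fill of the gaps, all three indices in one least squares
    gaps <- which(!validm[n, ])
    X <- harmonic_design(tv, K, period)
    qx <- qr(X)
    if (qx$rank < p)
      stop("harmonic reconstruction failed for sample ", n,
           ": rank-deficient design")
    beta <- qr.coef(qx, Y)
    fitted_gaps <- if (length(gaps))
      harmonic_design(doys[gaps], K, period) %*% beta else NULL
    for (k in 1:3) {
      out[[k]][n, iv] <- Y[, k]
      if (length(gaps)) out[[k]][n, gaps] <- fitted_gaps[, k]
    }
  }
  structure(list(index = out, doys = doys, valid = validm,
                 fill_fraction = rowMeans(!validm),
                 label = scene$label, class = scene$class,
                 polygon_id = scene$polygon_id),
            class = "recon_series")
}
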