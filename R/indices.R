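#' Normalized Difference Vegetation Index
#'
#' `ndvi()` contrasts near-infrared against red reflectance,
#' `(B8 - B4) / (B8 + B4)`. For paddy rice it rises sharply after
#' transplanting, peaks around tillering/heading and declines through grain
#' filling, which is the temporal signature the classifier exploits.
#'
#' All index functions are vectorized and guard the degenerate denominator:
#' where `|denominator| < tol` the value is emitted as 0 and the position is
#' recorded in the `"flagged"` attribute (a logical vector) so callers can
#' audit guarded pixels rather than receive NaN.
#'
#' @param b8 Near-infrared reflectance (Sentinel-2 B8), in `[0, 1]`.
#' @param b4 Red reflectance (Sentinel-2 B4), in `[0, 1]`.
#' @param tol Denominator guard threshold.
#' @return Numeric vector in `[-1, 1]` with attribute `"flagged"`.
#' @seealso [lswi()], [evi()], [tdvi()], [ncrvi()]
#' @export
#' @examples
#' ndvi(0.5, 0.1)   # 0.6667, dense canopy
#' ndvi(0.1, 0.5)   # -0.6667
ndvi <- function(b8, b4, tol = 1e-8) {
  normalized_difference(b8, b4, tol)
}

#' Land Surface Water Index
#'
#' `(B8 - B11) / (B8 + B11)`: near-infrared against shortwave infrared.
#' Sensitive to canopy/soil moisture; flooded paddies during transplanting
#' show high LSWI which then decays as fields dry toward harvest, separating
#' rice from upland crops.
#'
#' @inheritParams ndvi
#' @param b11 Shortwave-infrared reflectance (Sentinel-2 B11).
#' @return Numeric vector in `[-1, 1]` with attribute `"flagged"`.
#' @export
lswi <- function(b8, b11, tol = 1e-8) {
  normalized_difference(b8, b11, tol)
}

#' Enhanced Vegetation Index
#'
#' Three-band EVI, `2.5 (B8 - B4) / (B8 + 6 B4 - 7.5 B2 + 1)`, with the
#' standard gain and aerosol-resistance constants (G = 2.5, C1 = 6,
#' C2 = 7.5, L = 1). The blue band correction reduces soil-background and
#' atmospheric interference, keeping sensitivity at high biomass where NDVI
#' saturates.
#'
#' @inheritParams ndvi
#' @param b2 Blue reflectance (Sentinel-2 B2).
#' @return Numeric vector with attribute `"flagged"`.
#' @export
evi <- function(b8, b4, b2, tol = 1e-8) {
  den <- b8 + 6 * b4 - 7.5 * b2 + 1
  flagged <- !is.na(den) & abs(den) < tol
  out <- ifelse(flagged, 0, 2.5 * (b8 - b4) / den)
  structure(out, flagged = flagged)
}

#' Temporal Difference Vegetation Index
#'
#' Difference of a vegetation index between two consecutive observations,
#' `VI(t + dt) - VI(t)`. Positive values mark green-up (rapid canopy growth,
#' e.g. tillering), negative values mark senescence; the sign transitions
#' localize phenological stage boundaries.
#'
#' @param vi_t Index value at the earlier time.
#' @param vi_next Index value at the later time.
#' @return `vi_next - vi_t`.
#' @export
#' @examples
#' tdvi(0.3, 0.5)  #  0.2 green-up
#' tdvi(0.6, 0.4)  # -0.2 senescence
tdvi <- function(vi_t, vi_next) {
  vi_next - vi_t
}

#' Normalized Change Rate Vegetation Index
#'
#' Relative change of a vegetation index over an interval, as a percentage of
#' the starting value: `(VI(t2) - VI(t1)) / VI(t1) * 100`. Normalizing by the
#' baseline removes plot-to-plot fertility/management offsets, making growth
#' rates comparable across fields.
#'
#' Where `|VI(t1)| < guard` the rate is undefined; 0 is emitted and the
#' position flagged (attribute `"flagged"`).
#'
#' @param vi_t1 Index value at the start of the interval.
#' @param vi_t2 Index value at the end of the interval.
#' @param guard Near-zero baseline guard.
#' @return Percent change, numeric with attribute `"flagged"`.
#' @export
#' @examples
#' ncrvi(0.4, 0.5)  # +25
#' ncrvi(0.5, 0.4)  # -20
ncrvi <- function(vi_t1, vi_t2, guard = 1e-6) {
  flagged <- !is.na(vi_t1) & abs(vi_t1) < guard
  out <- ifelse(flagged, 0, (vi_t2 - vi_t1) / vi_t1 * 100)
  structure(out, flagged = flagged)
}

# shared core for the two normalized-difference indices
normalized_difference <- function(a, b, tol) {
  den <- a + b
  flagged <- !is.na(den) & abs(den) < tol
  out <- ifelse(flagged, 0, (a - b) / den)
  structure(out, flagged = flagged)
}
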