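#' Phenology parameters for a seasonal crop trajectory
#'
#' Describes a single-season crop curve by its calendar (transplanting date
#' and stage durations, in days) and its spectral amplitude (NDVI baseline
#' and peak, LSWI flooded and dry levels). Defaults describe single-season
#' japonica rice: transplanting in early/mid June (around day-of-year 160)
#' lasting 15--20 days, a growth period of roughly 85--95 days covering
#' tillering through heading, and a 40--45 day ripening period ending in
#' late-October harvest.
#'
#' @param transplant_doy Day of year transplanting starts.
#' @param transplant_len Transplanting/establishment duration, days (10--30).
#' @param growth_len Growth duration, days (60--110).
#' @param ripen_len Ripening duration, days (30--60).
#' @param ndvi_base NDVI at transplanting (sparse canopy over water/soil).
#' @param ndvi_peak NDVI at full canopy; must exceed `ndvi_base`.
#' @param lswi_flood LSWI while fields are flooded.
#' @param lswi_dry LSWI after fields drain.
#' @param noise_sd Per-observation Gaussian noise on index values.
#' @return A `phenology_params` list.
#' @export
phenology_params <- function(transplant_doy = 160, transplant_len = 18,
                             growth_len = 90, ripen_len = 42,
                             ndvi_base = 0.35, ndvi_peak = 0.85,
                             lswi_flood = 0.35, lswi_dry = 0.02,
                             noise_sd = 0.02) {
  stopifnot(
    transplant_len >= 10, transplant_len <= 30,
    growth_len >= 60, growth_len <= 110,
    ripen_len >= 30, ripen_len <= 60,
    ndvi_peak > ndvi_base,
    abs(ndvi_base) <= 1, abs(ndvi_peak) <= 1,
    abs(lswi_flood) <= 1, abs(lswi_dry) <= 1,
    noise_sd >= 0
  )
  structure(list(transplant_doy = transplant_doy,
                 transplant_len = transplant_len,
                 growth_len = growth_len, ripen_len = ripen_len,
                 ndvi_base = ndvi_base, ndvi_peak = ndvi_peak,
                 lswi_flood = lswi_flood, lswi_dry = lswi_dry,
                 noise_sd = noise_sd),
            class = "phenology_params")
}

# Template parameters for the non-rice land covers. Flat classes carry
# constant index levels; `other_crop` is a rain-fed confuser with a
# rice-like canopy curve shifted ~5 weeks earlier and no flooding signal.
default_class_templates <- function() {
  list(
    rice = list(type = "crop", params = phenology_params()),
    water = list(type = "flat", ndvi = -0.15, lswi = 0.55, noise_sd = 0.02),
    urban = list(type = "flat", ndvi = 0.12, lswi = -0.05, noise_sd = 0.02),
    forest = list(type = "seasonal", ndvi_mean = 0.62, ndvi_amp = 0.13,
                  lswi_mean = 0.18, lswi_amp = 0.05, peak_doy = 200,
                  noise_sd = 0.02),
    other_crop = list(type = "crop",
                      params = phenology_params(transplant_doy = 125,
                                                ndvi_base = 0.30,
                                                ndvi_peak = 0.80,
                                                lswi_flood = 0.08,
                                                lswi_dry = 0.0))
  )
}

#' Synthetic scene configuration
#'
#' Defines a labeled synthetic satellite-image-time-series scene with the
#' acquisition cadence of Sentinel-2 over a single rice season: a 5-day
#' revisit from day-of-year 152 (early June) to 304 (late October), cloud
#' losses injected at `gap_rate`, and sample points grouped into field
#' polygons (points of one polygon share jittered phenology, emulating
#' spatial correlation within a field).
#'
#' By default half of the polygons are rice and the remainder is split
#' evenly over water, urban, forest and a phase-shifted confuser crop, so
#' that the binary rice / non-rice labels are balanced.
#'
#' @param n_polygons Total number of polygons over all classes.
#' @param points_per_polygon Sample points drawn inside each polygon.
#' @param classes Optional named list overriding the default class mix; each
#'   entry is `list(n_polygons =, template =)` with a template as produced
#'   by [default_class_templates()].
#' @param doy_start,doy_end,revisit Acquisition grid (days of year).
#' @param gap_rate Expected fraction of cloud-lost observations, in `[0, 1)`.
#' @param patch_size Odd spatial patch width for the optional patch tensors.
#' @param make_patches Generate `P x P` neighborhoods around each point
#'   (memory-heavy; intended for small scenes).
#' @param seed Integer seed; the scene is a pure function of this config.
#' @return A `scene_config` object.
#' @export
scene_config <- function(n_polygons = 10000, points_per_polygon = 3,
                         classes = NULL, doy_start = 152, doy_end = 304,
                         revisit = 5, gap_rate = 0.3, patch_size = 5,
                         make_patches = FALSE, seed = 42) {
  stopifnot(revisit >= 1, gap_rate >= 0, gap_rate < 1,
            patch_size >= 1, patch_size %% 2 == 1,
            points_per_polygon >= 1)
  if (is.null(classes)) {
    if (n_polygons < 10) stop("need at least 10 polygons for the default class mix")
    templates <- default_class_templates()
    n_rice <- n_polygons %/% 2
    rest <- n_polygons - n_rice
    others <- setdiff(names(templates), "rice")
    n_each <- rep(rest %/% length(others), length(others))
    extra <- rest - sum(n_each)
    if (extra > 0) n_each[seq_len(extra)] <- n_each[seq_len(extra)] + 1
    classes <- c(
      list(rice = list(n_polygons = n_rice, template = templates$rice)),
      stats::setNames(
        lapply(seq_along(others), function(i)
          list(n_polygons = n_each[i], template = templates[[others[i]]])),
        others)
    )
  }
  np <- vapply(classes, function(x) x$n_polygons, numeric(1))
  if (any(np < 1)) stop("every class needs at least one polygon")
  structure(list(classes = classes, points_per_polygon = points_per_polygon,
                 doy_start = doy_start, doy_end = doy_end, revisit = revisit,
                 gap_rate = gap_rate, patch_size = patch_size,
                 make_patches = make_patches, seed = seed,
                 n_polygons = sum(np)),
            class = "scene_config")
}

# Double-logistic canopy curve. Vectorized over polygons: every parameter
# may be a length-P vector; returns a P x T matrix.
# Green-up ramp centered at 45% of the growth period, senescence ramp
# centered past the growth/ripening boundary, rates tied to the stage
# durations so the curve increases throughout growth and declines
# throughout ripening.
double_logistic_curve <- function(doys, transplant_doy, transplant_len,
                                  growth_len, ripen_len, base, peak) {
  t1 <- transplant_doy + transplant_len + 0.45 * growth_len
  r1 <- 0.16 * growth_len
  growth_end <- transplant_doy + transplant_len + growth_len
  t2 <- growth_end + 0.605 * ripen_len
  r2 <- ripen_len / 8
  up <- stats::plogis(outer(-t1, doys, `+`) / r1)
  down <- stats::plogis(outer(-t2, doys, `+`) / r2)
  base + (peak - base) * (up - down)
}

# Flood-drawdown curve for LSWI: stays near the flooded level through
# transplanting and most of the growth period, then drains toward the dry
# level as the fields are drawn down before ripening.
flood_drawdown_curve <- function(doys, transplant_doy, transplant_len,
                                 growth_len, flood, dry) {
  t_drain <- transplant_doy + transplant_len + 0.7 * growth_len
  s <- stats::plogis(outer(-t_drain, doys, `+`) / 12)
  flood + (dry - flood) * s
}

# Noiseless index curves for one class, vectorized over polygons.
# `jitter` is a list of per-polygon parameter offsets (may be zeros).
class_curves <- function(template, doys, n_poly = 1L,
                         jitter = NULL) {
  T_ <- length(doys)
  zero <- rep(0, n_poly)
  j <- function(name) if (is.null(jitter)) zero else jitter[[name]]
  if (template$type == "crop") {
    p <- template$params
    nd <- double_logistic_curve(doys,
                                p$transplant_doy + j("doy"), p$transplant_len,
                                p$growth_len, p$ripen_len,
                                p$ndvi_base + j("base"),
                                pmin(p$ndvi_peak + j("peak"), 0.98))
    lw <- flood_drawdown_curve(doys, p$transplant_doy + j("doy"),
                               p$transplant_len, p$growth_len,
                               p$lswi_flood + j("lswi"), p$lswi_dry)
  } else if (template$type == "flat") {
    nd <- matrix(template$ndvi + j("base"), n_poly, T_)
    lw <- matrix(template$lswi + j("lswi"), n_poly, T_)
  } else if (template$type == "seasonal") {
    season <- cos(2 * pi * (doys - template$peak_doy) / 365)
    nd <- (template$ndvi_mean + j("base")) +
      outer(rep(template$ndvi_amp, n_poly), season)
    lw <- (template$lswi_mean + j("lswi")) +
      outer(rep(template$lswi_amp, n_poly), season)
  } else stop("unknown class template type: ", template$type)
  list(ndvi = pmin(pmax(nd, -1), 1), lswi = pmin(pmax(lw, -1), 1))
}

#' Simulate noiseless or noisy index trajectories for one land-cover class
#'
#' Returns the per-observation NDVI and LSWI curves of the named class at
#' the given days of year. Rice follows a double-logistic canopy curve (near
#' `ndvi_base` at transplanting, rising through the growth period to
#' `ndvi_peak`, declining through ripening) with a flood-drawdown LSWI
#' (starting at `lswi_flood`, draining toward `lswi_dry`); water, urban and
#' forest use flat or mildly seasonal templates; `other_crop` is the
#' phase-shifted rain-fed confuser. Gaussian noise with the template's
#' `noise_sd` is added (uses the current RNG state; seed upstream for
#' reproducibility).
#'
#' @param class_name One of `"rice"`, `"water"`, `"urban"`, `"forest"`,
#'   `"other_crop"`.
#' @param params A [phenology_params()] for crop classes; ignored for flat
#'   templates. `NULL` uses the class default.
#' @param doys Increasing days of year in `[1, 366]`.
#' @param noise_sd Overrides the template noise standard deviation.
#' @return `list(ndvi =, lswi =)`, numeric vectors along `doys`.
#' @export
#' @examples
#' doys <- seq(152, 304, by = 5)
#' tr <- simulate_trajectory("rice", doys = doys, noise_sd = 0)
#' plot(doys, tr$ndvi, type = "l")
simulate_trajectory <- function(class_name, params = NULL,
                                doys = seq(152, 304, by = 5),
                                noise_sd = NULL) {
  stopifnot(all(doys >= 1), all(doys <= 366), !is.unsorted(doys, strictly = TRUE))
  templates <- default_class_templates()
  if (!class_name %in% names(templates))
    stop("unknown class_name: ", class_name)
  template <- templates[[class_name]]
  if (!is.null(params)) {
    if (template$type != "crop")
      stop("phenology params apply only to crop classes")
    template$params <- params
  }
  sd_ <- if (!is.null(noise_sd)) noise_sd
  else if (template$type == "crop") template$params$noise_sd
  else template$noise_sd
  cur <- class_curves(template, doys)
  noise <- function(x) x + stats::rnorm(length(x), 0, sd_)
  list(ndvi = pmin(pmax(noise(drop(cur$ndvi)), -1), 1),
       lswi = pmin(pmax(noise(drop(cur$lswi)), -1), 1))
}

#' Invert index values to band reflectances
#'
#' Produces Sentinel-2-like band reflectances whose recomputed indices
#' reproduce the requested NDVI and LSWI: given near-infrared `B8`,
#' `B4 = B8 (1 - ndvi) / (1 + ndvi)` and `B11 = B8 (1 - lswi) / (1 + lswi)`,
#' all clipped to `[0, 1]`. The blue band is a flat low level (soils and
#' canopies are dark in blue), which closes the loop for EVI as well.
#'
#' @param ndvi,lswi Target index values, strictly inside `(-1, 1)`.
#' @param b8_profile Near-infrared reflectance, scalar or vector along the
#'   series, in `(0, 1)`.
#' @param b2_level Blue reflectance level (default 0.04).
#' @return `list(B2, B4, B8, B11)` of reflectances in `[0, 1]`.
#' @export
invert_bands <- function(ndvi, lswi, b8_profile, b2_level = 0.04) {
  if (any(abs(ndvi) >= 1) || any(abs(lswi) >= 1))
    stop("ndvi and lswi must lie strictly inside (-1, 1) for band inversion")
  stopifnot(all(b8_profile > 0), all(b8_profile < 1))
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  b8 <- b8_profile + 0 * ndvi
  list(B2 = clip01(b2_level + 0 * ndvi),
       B4 = clip01(b8 * (1 - ndvi) / (1 + ndvi)),
       B8 = clip01(b8),
       B11 = clip01(b8 * (1 - lswi) / (1 + lswi)))
}

# Near-infrared profile used by the generator: brighter under dense canopy.
b8_from_ndvi <- function(ndvi) 0.10 + 0.38 * pmax(ndvi, 0)

#' Inject cloud-induced missingness into quality codes
#'
#' Marks each observation as cloud-lost independently with probability
#' `gap_rate` by setting its scene-classification code to the
#' high-probability-cloud code (9); clear observations keep code 4
#' (vegetation). At least one clear observation is always retained per
#' sample (a fully clouded series carries no information and is never
#' emitted). Uses the current RNG state.
#'
#' @param quality Integer matrix, samples x timesteps, of quality codes.
#' @param gap_rate Cloud loss probability in `[0, 1)`.
#' @param cloud_code Code written at lost observations.
#' @return Modified quality matrix.
#' @export
inject_gaps <- function(quality, gap_rate, cloud_code = 9L) {
  if (gap_rate >= 1) stop("gap_rate must be < 1")
  if (gap_rate == 0) return(quality)
  q <- as.matrix(quality)
  hit <- matrix(stats::runif(length(q)) < gap_rate, nrow(q), ncol(q))
  # retain at least one clear step per sample
  all_hit <- rowSums(!hit) == 0
  if (any(all_hit)) {
    keep <- sample.int(ncol(q), sum(all_hit), replace = TRUE)
    hit[cbind(which(all_hit), keep)] <- FALSE
  }
  q[hit] <- cloud_code
  q
}

#' Build a labeled synthetic scene
#'
#' Generates the full dataset described by a [scene_config()]: per-polygon
#' jittered phenology (shared by the polygon's points, giving within-field
#' correlation), per-point observation noise, band reflectances consistent
#' with the class index curves, cloud gaps, and binary labels (rice = 1).
#' The result is a pure function of the config, including its seed.
#'
#' @param config A [scene_config()].
#' @return A `rice_scene` object: list with `bands` (N x T x 4 array,
#'   B2/B4/B8/B11), `doys` (length-T), `quality` (N x T codes), `label`,
#'   `class`, `polygon_id` (length-N), `truth` (noiseless NDVI/LSWI
#'   matrices), optional `patches` (N x P x P x 4 x T), and the `config`.
#' @export
build_dataset <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  doys <- as.integer(seq(config$doy_start, config$doy_end, by = config$revisit))
  T_ <- length(doys)
  k <- config$points_per_polygon

  bands_list <- list(); meta <- list(); truth_nd <- list(); truth_lw <- list()
  poly_offset <- 0L
  for (cls in names(config$classes)) {
    spec <- config$classes[[cls]]
    P <- spec$n_polygons
    template <- spec$template
    # polygon-level parameter jitter: shared by the polygon's points
    jitter <- list(doy = stats::rnorm(P, 0, 4),
                   base = stats::rnorm(P, 0, 0.02),
                   peak = stats::rnorm(P, 0, 0.03),
                   lswi = stats::rnorm(P, 0, 0.03))
    cur <- class_curves(template, doys, n_poly = P, jitter = jitter)
    n <- P * k
    idx <- rep(seq_len(P), each = k)
    sd_ <- if (template$type == "crop") template$params$noise_sd else template$noise_sd
    nd <- cur$ndvi[idx, , drop = FALSE] +
      matrix(stats::rnorm(n * T_, 0, sd_), n, T_)
    lw <- cur$lswi[idx, , drop = FALSE] +
      matrix(stats::rnorm(n * T_, 0, sd_), n, T_)
    nd <- pmin(pmax(nd, -0.99), 0.99)
    lw <- pmin(pmax(lw, -0.99), 0.99)
    b <- invert_bands(nd, lw, b8_from_ndvi(nd))
    bands_list[[cls]] <- b
    truth_nd[[cls]] <- cur$ndvi[idx, , drop = FALSE]
    truth_lw[[cls]] <- cur$lswi[idx, , drop = FALSE]
    meta[[cls]] <- data.frame(class = cls,
                              label = as.integer(cls == "rice"),
                              polygon_id = as.integer(poly_offset + idx))
    poly_offset <- poly_offset + P
  }

  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  N <- nrow(meta)
  bands <- array(0, dim = c(N, T_, 4),
                 dimnames = list(NULL, NULL, c("B2", "B4", "B8", "B11")))
  row0 <- 0L
  for (cls in names(bands_list)) {
    b <- bands_list[[cls]]
    nr <- nrow(b$B2)
    rows <- row0 + seq_len(nr)
    bands[rows, , 1] <- b$B2; bands[rows, , 2] <- b$B4
    bands[rows, , 3] <- b$B8; bands[rows, , 4] <- b$B11
    row0 <- row0 + nr
  }

  quality <- matrix(4L, N, T_)
  quality <- inject_gaps(quality, config$gap_rate)

  scene <- list(bands = bands, doys = doys, quality = quality,
                label = meta$label, class = meta$class,
                polygon_id = meta$polygon_id,
                truth = list(ndvi = do.call(rbind, truth_nd),
                             lswi = do.call(rbind, truth_lw)),
                config = config)
  if (config$make_patches) scene$patches <- make_patches(scene)
  structure(scene, class = "rice_scene")
}

# P x P spatial neighborhoods: the center pixel's bands plus independent
# spatial noise, clipped to [0, 1]. Only for small scenes.
make_patches <- function(scene, spatial_sd = 0.01) {
  P <- scene$config$patch_size
  N <- dim(scene$bands)[1]; T_ <- dim(scene$bands)[2]
  out <- array(0, dim = c(N, P, P, 4, T_))
  for (i in seq_len(P)) for (j in seq_len(P)) {
    noise <- if (i == (P + 1) / 2 && j == (P + 1) / 2) 0 else
      array(stats::rnorm(N * T_ * 4, 0, spatial_sd), dim = c(N, T_, 4))
    out[, i, j, , ] <- aperm(pmin(pmax(scene$bands + noise, 0), 1), c(1, 3, 2))
  }
  out
}

#' @export
print.rice_scene <- function(x, ...) {
  cat("rice_scene:", dim(x$bands)[1], "samples x", dim(x$bands)[2],
      "timesteps,", length(unique(x$polygon_id)), "polygons\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$class)),
                                  table(x$class)), collapse = ", "), "\n")
  cat("  doys", min(x$doys), "-", max(x$doys),
      sprintf("| clouded %.1f%%\n", 100 * mean(x$quality != 4L)))
  invisible(x)
}

#' Write / read a scene as a long-format CSV
#'
#' One row per sample and timestep with columns `sample_id`, `polygon_id`,
#' `class`, `label`, `doy`, `B2`, `B4`, `B8`, `B11`, `quality`. Values
#' round-trip at full double precision. Patch tensors are not serialized.
#'
#' @param scene A `rice_scene`.
#' @param path Output CSV path.
#' @return `write_scene_csv` returns `path` invisibly; `read_scene_csv`
#'   returns a `rice_scene` (without `truth`/`patches`/`config`).
#' @export
write_scene_csv <- function(scene, path) {
  N <- dim(scene$bands)[1]; T_ <- dim(scene$bands)[2]
  dt <- data.table::data.table(
    sample_id = rep(seq_len(N), each = T_),
    polygon_id = rep(scene$polygon_id, each = T_),
    class = rep(scene$class, each = T_),
    label = rep(scene$label, each = T_),
    doy = rep(scene$doys, times = N),
    B2 = as.vector(t(scene$bands[, , 1])),
    B4 = as.vector(t(scene$bands[, , 2])),
    B8 = as.vector(t(scene$bands[, , 3])),
    B11 = as.vector(t(scene$bands[, , 4])),
    quality = as.vector(t(scene$quality)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_scene_csv
#' @param path Input CSV path.
#' @export
read_scene_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample_id", "polygon_id", "class", "label", "doy",
            "B2", "B4", "B8", "B11", "quality")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("malformed scene CSV, missing columns: ",
                         paste(miss, collapse = ", "))
  ids <- unique(dt$sample_id)
  doys <- sort(unique(dt$doy))
  T_ <- length(doys); N <- length(ids)
  ord <- order(match(dt$sample_id, ids), dt$doy)
  dt <- dt[ord]
  bands <- array(0, dim = c(N, T_, 4),
                 dimnames = list(NULL, NULL, c("B2", "B4", "B8", "B11")))
  for (b in 1:4) bands[, , b] <- matrix(dt[[c("B2", "B4", "B8", "B11")[b]]],
                                        N, T_, byrow = TRUE)
  first <- !duplicated(dt$sample_id)
  structure(list(bands = bands, doys = doys,
                 quality = matrix(dt$quality, N, T_, byrow = TRUE),
                 label = dt$label[first], class = dt$class[first],
                 polygon_id = dt$polygon_id[first]),
            class = "rice_scene")
}
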