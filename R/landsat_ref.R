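#' Select pure sample locations by systematic random sampling
#'
#' Eligible cells are those of the requested biome whose class is constant
#' across the supplied yearly maps. The eligible cells (in grid order) are
#' divided into `count` equal strata and one seeded draw is taken per
#' stratum — systematic random sampling. When fewer eligible cells than
#' requested exist, all are returned with a warning.
#'
#' @param major_biome a [biome_map()] (the majority map).
#' @param counts named integer vector: requested locations per biome name
#'   (e.g. `c(GRA = 100, DNF = 70)`); the deciduous-needleleaf class is
#'   conventionally requested at 0.7 times the other biomes.
#' @param yearly_maps optional list of yearly [biome_map()]s defining the
#'   constant-class constraint (default: no constraint beyond the major map).
#' @param seed RNG seed.
#' @return data.frame of locations: `row`, `col`, `lat`, `lon`, `biome`.
#' @export
select_sample_locations <- function(major_biome, counts, yearly_maps = NULL,
                                    seed = 1L) {
  g <- major_biome$grid
  constant <- matrix(TRUE, g$nrow, g$ncol)
  if (!is.null(yearly_maps))
    for (m in yearly_maps) constant <- constant & m$codes == major_biome$codes
  latc <- lat_centers(g); lonc <- lon_centers(g)
  out <- list()
  with_rng(seed, {
    for (bn in names(counts)) {
      code <- BIOME_CODES[[bn]]
      eligible <- which(major_biome$codes == code & constant)
      want <- counts[[bn]]
      if (want < 1) next
      if (length(eligible) <= want) {
        if (length(eligible) < want)
          warning(sprintf("%s: only %d eligible cells for %d requested",
                          bn, length(eligible), want))
        pick <- eligible
      } else {
        edges <- floor(seq(0, length(eligible), length.out = want + 1))
        pick <- vapply(seq_len(want), function(s) {
          pool <- eligible[(edges[s] + 1):edges[s + 1]]
          pool[sample.int(length(pool), 1L)]
        }, numeric(1))
      }
      if (!length(pick)) next
      rc <- arrayInd(pick, c(g$nrow, g$ncol))
      out[[bn]] <- data.frame(row = rc[, 1], col = rc[, 2],
                              lat = latc[rc[, 1]], lon = lonc[rc[, 2]],
                              biome = code)
    }
  })
  if (!length(out))
    return(data.frame(row = integer(0), col = integer(0), lat = numeric(0),
                      lon = numeric(0), biome = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen a reflectance patch for quality
#'
#' A patch passes when its good-pixel fraction is at least 90% (patches
#' with *less than* 90% are excluded) and its atmospheric opacity does not
#' exceed the threshold.
#'
#' @param patch a `landsat_patch`.
#' @param aop_max AOP threshold (default 0.3).
#' @return logical.
#' @export
screen_patch_quality <- function(patch, aop_max = 0.3) {
  mean(patch$qa) >= 0.90 && patch$aop <= aop_max
}

#' Aggregate a patch to one reflectance per band
#'
#' Per-band mean over the good-quality pixels.
#'
#' @param patch a `landsat_patch`.
#' @return named numeric vector of six band reflectances.
#' @export
aggregate_patch_reflectance <- function(patch) {
  good <- as.vector(patch$qa)
  v <- vapply(1:6, function(k) mean(patch$bands[, , k][good]), numeric(1))
  names(v) <- BAND_NAMES
  v
}

#' Homogeneity screen by the coefficient of variation
#'
#' Per-band CV (sd/mean over good pixels); the patch passes when the mean
#' CV across the six bands is strictly below 0.15. A zero-mean band makes
#' the CV undefined and fails the patch.
#'
#' @param patch a `landsat_patch`.
#' @param cv_max mean-CV threshold (strict `<`, default 0.15).
#' @return list with `cv` (six per-band CVs), `mean_cv`, `pass`.
#' @export
homogeneity_cv_filter <- function(patch, cv_max = 0.15) {
  good <- as.vector(patch$qa)
  cv <- vapply(1:6, function(k) {
    px <- patch$bands[, , k][good]
    m <- mean(px)
    if (m == 0) return(NA_real_)
    stats::sd(px) / m
  }, numeric(1))
  names(cv) <- BAND_NAMES
  mean_cv <- mean(cv)
  list(cv = cv, mean_cv = mean_cv,
       pass = is.finite(mean_cv) && mean_cv < cv_max)
}

#' Vegetation indices from six-band reflectance
#'
#' NDVI, EVI, EVI2 and NDWI in their standard forms (NDWI in Gao's
#' NIR/SWIR1 form). Zero denominators yield `NA`.
#'
#' @param reflectance named numeric vector with at least `blue`, `red`,
#'   `nir`, `swir1`.
#' @return named numeric vector `c(ndvi, evi, evi2, ndwi)`.
#' @export
vegetation_indices <- function(reflectance) {
  r <- as.list(reflectance)
  safe <- function(num, den) if (!is.na(den) && abs(den) > 0) num / den else NA_real_
  c(ndvi = safe(r$nir - r$red, r$nir + r$red),
    evi = safe(2.5 * (r$nir - r$red), r$nir + 6 * r$red - 7.5 * r$blue + 1),
    evi2 = safe(2.5 * (r$nir - r$red), r$nir + 2.4 * r$red + 1),
    ndwi = safe(r$nir - r$swir1, r$nir + r$swir1))
}

# Assemble the 14-feature row of a screened, aggregated patch.
reference_features <- function(refl, patch) {
  vi <- vegetation_indices(refl)
  c(refl, vi, lat = patch$lat, lon = patch$lon,
    solar_zenith = patch$solar_zenith, view_zenith = patch$view_zenith)
}

#' Build reference sample pairs from patches and the benchmark
#'
#' Screens each patch (quality then homogeneity), aggregates it to one
#' six-band reflectance, derives the vegetation indices, and matches it to
#' the benchmark FPAR value of its cell and half-month. Pairs sharing a
#' location and acquisition stamp are averaged.
#'
#' @param patches list of `landsat_patch`es.
#' @param benchmark FPAR `raster_cube`.
#' @param biome a [biome_map()].
#' @param aop_max,cv_max screening thresholds.
#' @return data.frame of reference pairs (six bands, four indices, lat,
#'   lon, angles, sensor, biome, year, period, `fpar` target).
#' @export
build_reference_pairs <- function(patches, benchmark, biome, aop_max = 0.3,
                                  cv_max = 0.15) {
  rows <- list()
  for (p in patches) {
    if (!screen_patch_quality(p, aop_max)) next
    if (!homogeneity_cv_filter(p, cv_max)$pass) next
    t <- cube_scene_index(benchmark, p$year, p$period)
    if (is.na(t)) next
    target <- benchmark$values[t, p$row, p$col]
    if (is.na(target)) next
    refl <- aggregate_patch_reflectance(p)
    feat <- reference_features(refl, p)
    rows[[length(rows) + 1L]] <- data.frame(
      t(feat), sensor = p$sensor, biome = biome$codes[p$row, p$col],
      year = p$year, period = p$period, fpar = target)
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  key <- paste(df$lat, df$lon, df$year, df$period, df$sensor)
  num <- setdiff(names(df), c("sensor", "biome", "year", "period"))
  agg <- stats::aggregate(df[num], by = list(key = key), FUN = mean)
  first <- df[!duplicated(key), c("sensor", "biome", "year", "period")]
  cbind(agg[match(unique(key), agg$key), num, drop = FALSE], first)
}

#' Train a random-forest reference regressor for one biome x sensor stratum
#'
#' 200 trees, split-candidate count one third of the 14 features (rounded
#' up), minimum 5 observations per leaf; out-of-bag predictions provide the
#' reported metrics.
#'
#' @param pairs reference-pair data.frame of a single biome and sensor.
#' @param seed RNG seed.
#' @param ntree,nodesize forest settings.
#' @return list with the `forest`, `oob` (`metric_set`), `biome`, `sensor`.
#' @export
train_reference_regressor <- function(pairs, seed = 1L, ntree = 200L,
                                      nodesize = 5L) {
  if (length(unique(pairs$sensor)) != 1L || length(unique(pairs$biome)) != 1L)
    stop("pairs must come from a single biome x sensor stratum")
  feat_cols <- c(BAND_NAMES, "ndvi", "evi", "evi2", "ndwi",
                 "lat", "lon", "solar_zenith", "view_zenith")
  X <- pairs[, feat_cols]
  ok <- stats::complete.cases(X)
  X <- X[ok, ]; y <- pairs$fpar[ok]
  rf <- with_rng(seed,
    randomForest::randomForest(X, y, ntree = ntree,
                               mtry = ceiling(length(feat_cols) / 3),
                               nodesize = nodesize))
  list(forest = rf, oob = regression_metrics(rf$predicted, y),
       biome = pairs$biome[1], sensor = pairs$sensor[1], n = length(y))
}

#' Train the full bank of per-biome, per-sensor regressors
#'
#' @param pairs reference-pair data.frame across strata.
#' @param min_pairs minimum pairs per stratum (default 100).
#' @param seed RNG seed.
#' @return named list of regressors keyed `"biome.sensor"`.
#' @export
train_reference_regressors <- function(pairs, min_pairs = 100L, seed = 1L) {
  key <- paste(pairs$biome, pairs$sensor, sep = ".")
  out <- list()
  for (k in unique(key)) {
    sub <- pairs[key == k, , drop = FALSE]
    if (nrow(sub) < min_pairs) next
    out[[k]] <- train_reference_regressor(sub, seed = seed)
  }
  out
}

#' Predict high-resolution FPAR reference samples
#'
#' Each coarse (1/12 degree) pixel carries up to nine evenly distributed
#' patch locations per scene. Every location is screened, aggregated and
#' homogeneity-filtered, then predicted with the regressor of its biome and
#' sensor; a reference sample is emitted only when more than five of the
#' nine locations survive, as the mean of the valid predictions. Samples of
#' the same pixel falling in the same half-month are then averaged.
#'
#' @param models regressor bank from [train_reference_regressors()].
#' @param patch_groups list of patch lists, one per (pixel, scene); each
#'   group's patches share `row`, `col`, `year`, `period`.
#' @param biome a [biome_map()].
#' @param min_locations strict lower bound on valid locations (default 5:
#'   "more than 5").
#' @param aop_max,cv_max screening thresholds.
#' @return data.frame of reference samples: `lat`, `lon`, `row`, `col`,
#'   `year`, `period`, `fpar`, `n_locations`.
#' @export
predict_reference_samples <- function(models, patch_groups, biome,
                                      min_locations = 5L, aop_max = 0.3,
                                      cv_max = 0.15) {
  per_scene <- list()
  for (grp in patch_groups) {
    if (!length(grp)) next
    if (length(grp) > 9L) stop("at most nine locations per coarse pixel")
    preds <- numeric(0)
    for (p in grp) {
      if (!screen_patch_quality(p, aop_max)) next
      if (!homogeneity_cv_filter(p, cv_max)$pass) next
      key <- paste(biome$codes[p$row, p$col], p$sensor, sep = ".")
      if (is.null(models[[key]])) next
      refl <- aggregate_patch_reflectance(p)
      feat <- reference_features(refl, p)
      preds <- c(preds,
                 stats::predict(models[[key]]$forest,
                                newdata = as.data.frame(t(feat))))
    }
    if (length(preds) <= min_locations) next
    p1 <- grp[[1]]
    per_scene[[length(per_scene) + 1L]] <- data.frame(
      row = p1$row, col = p1$col, lat = p1$lat, lon = p1$lon,
      year = p1$year, period = p1$period,
      fpar = mean(preds), n_locations = length(preds))
  }
  if (!length(per_scene))
    return(data.frame(row = integer(0), col = integer(0), lat = numeric(0),
                      lon = numeric(0), year = integer(0), period = integer(0),
                      fpar = numeric(0), n_locations = integer(0)))
  df <- do.call(rbind, per_scene)
  key <- paste(df$row, df$col, df$year, df$period)
  agg <- stats::aggregate(df[c("fpar", "n_locations")],
                          by = list(key = key),
                          FUN = function(v) mean(v))
  meta <- df[!duplicated(key), c("row", "col", "lat", "lon", "year", "period")]
  res <- cbind(meta, agg[match(unique(key), agg$key), c("fpar", "n_locations")])
  res$n_locations <- as.integer(round(res$n_locations))
  rownames(res) <- NULL
  res
}

#' Lay out nine evenly distributed sub-locations in a coarse pixel
#'
#' @param grid a `grid_spec`.
#' @param row,col coarse cell indices.
#' @return data.frame of nine `lat`/`lon` points on a 3 x 3 sub-grid.
#' @export
nine_locations <- function(grid, row, col) {
  lat0 <- grid$lat_max - (row - 1) * grid$res
  lon0 <- grid$lon_min + (col - 1) * grid$res
  off <- (c(1, 3, 5) / 6) * grid$res
  expand.grid(lat = lat0 - off, lon = lon0 + off)
}
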