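#' Generate a yearly biome map
#'
#' Draws a spatially clustered categorical map: a coarse Gaussian random
#' field (seeded by the world seed) is upsampled to the full grid, rank-
#' transformed, and cut into the non-vegetated fraction plus equal shares of
#' the configured vegetated classes. A small, seeded fraction of cells is
#' re-drawn each year so that multi-year majority mapping is exercised; the
#' underlying field is the same for all years, so the per-cell modal class
#' over a stack of years recovers the base map.
#'
#' @param config a [world_config()].
#' @param year the year label; also seeds the year-specific class flips.
#' @return a [biome_map()].
#' @export
generate_biome_map <- function(config, year) {
  grid <- config$grid
  base <- with_rng(config$seed * 1000L + 1L, {
    cr <- max(3L, ceiling(grid$nrow / 8))
    cc <- max(3L, ceiling(grid$ncol / 8))
    coarse <- matrix(stats::rnorm(cr * cc), cr, cc)
    field <- regrid_matrix(coarse, c(grid$nrow, grid$ncol), method = "bicubic")
    u <- matrix(rank(field, ties.method = "first") / length(field),
                grid$nrow, grid$ncol)
    codes <- matrix(0L, grid$nrow, grid$ncol)
    veg <- u > config$nonveg_frac
    classes <- as.integer(config$biomes$code)
    share <- (u[veg] - config$nonveg_frac) / (1 - config$nonveg_frac)
    idx <- pmin(length(classes), 1L + floor(share * length(classes)))
    codes[veg] <- classes[idx]
    codes
  })
  if (config$flip_frac > 0) {
    base <- with_rng(config$seed * 1000L + 100L + (year - config$years[1]), {
      n <- length(base)
      k <- round(config$flip_frac * n)
      if (k > 0) {
        cells <- sample.int(n, k)
        pool <- c(0L, as.integer(config$biomes$code))
        repl <- sample(pool, k, replace = TRUE)
        # force an actual change where the draw matched the current class
        same <- repl == base[cells]
        repl[same] <- pool[(match(repl[same], pool) %% length(pool)) + 1L]
        base[cells] <- repl
      }
      base
    })
  }
  biome_map(base, grid, year = year)
}

#' Generate the true FPAR record
#'
#' The truth model is the minimal structure that makes the downstream
#' seasonal, trend and interannual diagnostics non-trivial:
#' `truth = biome mean + seasonal harmonic + pixel trend * (year - start)
#' + AR(1) yearly anomaly`, clipped to [0, 1]. The harmonic is a single
#' sine over the 24-period year (its annual mean is exactly zero) with the
#' phase shifted by half a year south of the equator; the AR(1) anomaly is
#' drawn per pixel and year and shared by all periods of that year.
#' Non-vegetated cells are fill.
#'
#' @param biome a [biome_map()] on the config grid.
#' @param config a [world_config()].
#' @return a `raster_cube` of FPAR truth over `config$years`.
#' @export
generate_truth_fpar <- function(biome, config) {
  grid <- config$grid
  if (!same_grid(grid, biome$grid)) stop("biome map grid does not match config")
  time <- make_time_axis(config$years)
  nt <- nrow(time); np <- grid$nrow * grid$ncol
  codes <- as.vector(biome$codes)
  bi <- match(codes, config$biomes$code)          # NA for non-vegetated
  mean_f <- config$biomes$mean_fpar[bi]
  amp <- config$biomes$amplitude[bi]
  phase <- config$biomes$phase[bi]
  south <- rep(lat_centers(grid), times = grid$ncol) < 0
  phase <- ifelse(south, phase + 12, phase)
  trend <- if (is.matrix(config$trend)) as.vector(config$trend)
           else rep(config$trend, np)
  nyr <- length(config$years)
  anom <- with_rng(config$seed * 1000L + 2L, {
    e <- matrix(stats::rnorm(nyr * np, sd = config$ar1_sd), nyr, np)
    a <- matrix(0, nyr, np)
    a[1, ] <- e[1, ]
    if (nyr > 1) for (y in 2:nyr) a[y, ] <- config$ar1_rho * a[y - 1, ] + e[y, ]
    a
  })
  vals <- array(NA_real_, c(nt, grid$nrow, grid$ncol))
  yr_idx <- time$year - config$years[1] + 1L
  for (t in seq_len(nt)) {
    p <- time$period[t]
    seas <- amp * sin(2 * pi * (p - phase) / 24)
    v <- mean_f + seas + trend * (yr_idx[t] - 1L) + anom[yr_idx[t], ]
    vals[t, , ] <- matrix(clip01(v), grid$nrow, grid$ncol)
  }
  raster_cube(vals, time, grid, varname = "fpar")
}

# Biome-specific monotone NDVI-FPAR link and its inverse:
#   fpar = a + (1 - a) * ndvi  <=>  ndvi = (fpar - a) / (1 - a)
link_fpar_from_ndvi <- function(ndvi, link_a) link_a + (1 - link_a) * ndvi
link_ndvi_from_fpar <- function(fpar, link_a) (fpar - link_a) / (1 - link_a)

#' Simulate the NDVI sensor record
#'
#' Passes the FPAR truth through the inverse of the biome-specific monotone
#' link, adds observation noise, and (optionally) imprints the mission-era
#' artifact schedule: a multiplicative drift ramp within each era and an
#' additive offset switched in at each platform change. With
#' `artifacts = FALSE` the output emulates a drift-corrected NDVI source;
#' with `artifacts = TRUE` it emulates a conventional AVHRR-era record.
#' A seeded fraction of observations is flagged unusable in the QC layer
#' (code 2); usable observations carry code 0 or 1.
#'
#' @param truth FPAR truth cube from [generate_truth_fpar()].
#' @param biome the [biome_map()] used to generate the truth.
#' @param config a [world_config()].
#' @param artifacts imprint drift/jump artifacts? (default TRUE)
#' @return an NDVI `raster_cube` restricted to years up to `config$ndvi_end`.
#' @export
simulate_sensor_ndvi <- function(truth, biome, config, artifacts = TRUE) {
  grid <- config$grid
  tr <- cube_subset_time(truth, years = config$years[1]:config$ndvi_end)
  nt <- nrow(tr$time)
  bi <- match(as.vector(biome$codes), config$biomes$code)
  link_a <- config$biomes$link_a[bi]
  vals <- array(NA_real_, dim(tr$values))
  for (t in seq_len(nt)) {
    v <- link_ndvi_from_fpar(as.vector(tr$values[t, , ]), link_a)
    vals[t, , ] <- matrix(v, grid$nrow, grid$ncol)
  }
  vals <- vals + with_rng(config$seed * 1000L + 3L + !artifacts,
                          array(stats::rnorm(length(vals), sd = config$ndvi_noise_sd),
                                dim(vals)))
  if (artifacts) {
    frac_year <- tr$time$year + (tr$time$period - 0.5) / 24
    for (e in seq_len(nrow(config$missions))) {
      m <- config$missions[e, ]
      in_era <- tr$time$year >= m$start & tr$time$year <= m$end
      if (!any(in_era)) next
      ramp <- 1 + m$drift * (frac_year[in_era] - m$start)
      vals[in_era, , ] <- vals[in_era, , , drop = FALSE] *
        array(rep(ramp, times = grid$nrow * grid$ncol),
              c(sum(in_era), grid$nrow, grid$ncol)) + m$jump
    }
  }
  vals <- pmin(pmax(vals, -1), 1)
  qc <- with_rng(config$seed * 1000L + 5L, {
    q <- array(sample(0:1, length(vals), replace = TRUE), dim(vals))
    q[array(stats::runif(length(vals)), dim(vals)) < config$qc_bad_frac] <- 2L
    q[is.na(vals)] <- 2L
    q
  })
  raster_cube(vals, tr$time, grid, qc = qc, varname = "ndvi")
}

#' Simulate the benchmark FPAR record
#'
#' Truth plus i.i.d. observation noise, clipped to [0, 1] and restricted to
#' the benchmark availability span. Occasional negative spikes are injected
#' into evergreen broadleaf forest pixels (when a biome map is supplied) to
#' exercise the one-sided outlier down-weighting of the smoothing filter;
#' their positions are recorded in the `spikes` attribute.
#'
#' @param truth FPAR truth cube.
#' @param config a [world_config()].
#' @param noise_sd observation noise sd (default from config).
#' @param start_year first benchmark year (default from config).
#' @param biome optional [biome_map()]; needed for spike injection.
#' @param spike_frac fraction of EBF (time, pixel) entries spiked.
#' @param spike_mag magnitude subtracted at a spike.
#' @return an FPAR `raster_cube` covering `start_year` onwards.
#' @export
simulate_si_fpar <- function(truth, config, noise_sd = config$benchmark_noise_sd,
                             start_year = config$benchmark_start,
                             biome = NULL, spike_frac = 0.005, spike_mag = 0.3) {
  if (!(start_year %in% config$years)) stop("start_year outside the truth span")
  tr <- cube_subset_time(truth, years = start_year:max(config$years))
  vals <- tr$values
  if (noise_sd > 0)
    vals <- vals + with_rng(config$seed * 1000L + 6L,
                            array(stats::rnorm(length(vals), sd = noise_sd), dim(vals)))
  spikes <- NULL
  if (!is.null(biome) && spike_frac > 0 && spike_mag > 0) {
    ebf <- which(biome$codes == BIOME_CODES[["EBF"]])
    if (length(ebf)) {
      nt <- nrow(tr$time)
      spikes <- with_rng(config$seed * 1000L + 7L, {
        cand <- expand.grid(t = seq_len(nt), cell = ebf)
        k <- max(1L, round(spike_frac * nrow(cand)))
        cand[sample.int(nrow(cand), k), ]
      })
      rc <- arrayInd(spikes$cell, c(tr$grid$nrow, tr$grid$ncol))
      idx <- cbind(spikes$t, rc)
      vals[idx] <- vals[idx] - spike_mag
      spikes <- data.frame(t = spikes$t, row = rc[, 1], col = rc[, 2])
    }
  }
  vals <- clip01(vals)
  out <- raster_cube(vals, tr$time, tr$grid, varname = "fpar")
  attr(out, "spikes") <- spikes
  out
}

# Six-band reflectance response to FPAR: visible and shortwave-infrared
# reflectance fall with canopy density, near-infrared rises.
BAND_NAMES <- c("blue", "green", "red", "nir", "swir1", "swir2")
BAND_BASE <- c(blue = 0.06, green = 0.08, red = 0.08, nir = 0.12,
               swir1 = 0.20, swir2 = 0.16)
BAND_GAIN <- c(blue = -0.03, green = -0.02, red = -0.06, nir = 0.30,
               swir1 = -0.12, swir2 = -0.10)
SENSOR_OFFSET <- rbind(
  TM    = c(0, 0, 0, 0, 0, 0),
  `ETM+` = c(0.004, 0.003, 0.004, -0.005, 0.003, 0.002),
  OLI   = c(-0.003, -0.002, -0.004, 0.006, -0.002, -0.003))
colnames(SENSOR_OFFSET) <- BAND_NAMES

sensors_for_year <- function(year) {
  s <- character(0)
  if (year >= 1984 && year <= 2011) s <- c(s, "TM")
  if (year >= 1999) s <- c(s, "ETM+")
  if (year >= 2013) s <- c(s, "OLI")
  if (!length(s)) s <- "TM"
  s
}

#' Simulate high-resolution reflectance patches
#'
#' For each requested location (and acquisition stamp) generates a 20 x 20
#' six-band reflectance patch from the local truth FPAR through a band-wise
#' monotone response, plus multiplicative spatial texture whose coefficient
#' of variation is set by `heterogeneity`. Per-sensor band offsets
#' differentiate the three emulated sensors; a per-pixel QA mask and a
#' per-patch atmospheric-opacity (AOP) scalar are drawn seeded.
#'
#' @param truth FPAR truth cube.
#' @param locations data.frame with `lat`, `lon` and optionally `year`,
#'   `period`, `sensor`; missing stamps are drawn seeded from the truth span.
#' @param config a [world_config()].
#' @param heterogeneity relative spatial texture level (sd/mean per band).
#' @param qa_bad_frac expected fraction of QA-bad pixels per patch.
#' @param patch_size patch edge length in pixels.
#' @param seed stream seed (default derived from the config seed).
#' @return a list of `landsat_patch` objects (locations whose pixel is fill
#'   at the stamp are dropped).
#' @export
simulate_landsat_patches <- function(truth, locations, config,
                                     heterogeneity = 0.05, qa_bad_frac = 0.05,
                                     patch_size = 20L,
                                     seed = config$seed * 1000L + 8L) {
  grid <- truth$grid
  cells <- cell_of(grid, locations$lat, locations$lon)
  if (any(is.na(cells$row))) stop("location outside grid bounds")
  with_rng(seed, {
    n <- nrow(locations)
    if (is.null(locations$year)) {
      sc <- sample.int(nrow(truth$time), n, replace = TRUE)
      locations$year <- truth$time$year[sc]
      locations$period <- truth$time$period[sc]
    }
    out <- vector("list", n)
    for (i in seq_len(n)) {
      t <- cube_scene_index(truth, locations$year[i], locations$period[i])
      if (is.na(t)) next
      f <- truth$values[t, cells$row[i], cells$col[i]]
      if (is.na(f)) next
      sensor <- if (!is.null(locations$sensor)) locations$sensor[i]
                else sample(sensors_for_year(locations$year[i]), 1L)
      mu <- pmax(0.005, BAND_BASE + BAND_GAIN * f + SENSOR_OFFSET[sensor, ])
      bands <- array(0, c(patch_size, patch_size, 6L),
                     dimnames = list(NULL, NULL, BAND_NAMES))
      for (k in 1:6) {
        px <- mu[k] * (1 + heterogeneity * stats::rnorm(patch_size^2))
        bands[, , k] <- matrix(clip01(px), patch_size, patch_size)
      }
      qa <- matrix(stats::runif(patch_size^2) >= qa_bad_frac,
                   patch_size, patch_size)
      out[[i]] <- structure(list(
        bands = bands, qa = qa,
        aop = stats::runif(1, 0, 0.5),
        solar_zenith = stats::runif(1, 20, 60),
        solar_azimuth = stats::runif(1, 0, 360),
        view_zenith = stats::runif(1, 0, 8),
        sensor = sensor, year = locations$year[i], period = locations$period[i],
        lat = locations$lat[i], lon = locations$lon[i],
        row = cells$row[i], col = cells$col[i]),
        class = "landsat_patch")
    }
    out[!vapply(out, is.null, logical(1))]
  })
}

#' Simulate ground measurement sites
#'
#' Places sites on random vegetated cells and records irregularly
#' subsampled visits whose value is the local truth plus noise.
#'
#' @param truth FPAR truth cube.
#' @param config a [world_config()].
#' @param n_sites number of sites (0 gives an empty frame).
#' @param noise_sd measurement noise sd.
#' @param visit_frac probability that a site reports in a given scene.
#' @param biome optional [biome_map()] for site biome labels.
#' @return a data.frame of measurements (site, lat, lon, year, period,
#'   fpar, biome, source).
#' @export
simulate_ground_sites <- function(truth, config, n_sites, noise_sd = 0.05,
                                  visit_frac = 0.2, biome = NULL) {
  empty <- data.frame(site = integer(0), lat = numeric(0), lon = numeric(0),
                      year = integer(0), period = integer(0),
                      fpar = numeric(0), biome = integer(0),
                      source = character(0))
  if (n_sites < 1) return(empty)
  grid <- truth$grid
  veg <- which(!apply(is.na(truth$values), c(2, 3), all))
  if (!length(veg)) return(empty)
  with_rng(config$seed * 1000L + 9L, {
    cells <- sample(veg, min(n_sites, length(veg)), replace = length(veg) < n_sites)
    rc <- arrayInd(cells, c(grid$nrow, grid$ncol))
    lat <- lat_centers(grid)[rc[, 1]]
    lon <- lon_centers(grid)[rc[, 2]]
    src <- sample(c("GBOV", "DIRECT", "VALERI", "ImagineS"),
                  length(cells), replace = TRUE)
    nt <- nrow(truth$time)
    rows <- vector("list", length(cells))
    for (s in seq_along(cells)) {
      visits <- which(stats::runif(nt) < visit_frac)
      if (!length(visits)) next
      v <- truth$values[cbind(visits, rc[s, 1], rc[s, 2])]
      keep <- !is.na(v)
      visits <- visits[keep]; v <- v[keep]
      if (!length(visits)) next
      rows[[s]] <- data.frame(
        site = s, lat = lat[s], lon = lon[s],
        year = truth$time$year[visits], period = truth$time$period[visits],
        fpar = clip01(v + stats::rnorm(length(v), sd = noise_sd)),
        biome = if (!is.null(biome)) biome$codes[rc[s, 1], rc[s, 2]] else NA_integer_,
        source = src[s])
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) empty else out
  })
}
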