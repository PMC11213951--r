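#' Default per-biome parameters of the synthetic world
#'
#' Mean FPAR, seasonal amplitude and phase, and the biome-specific monotone
#' NDVI-FPAR link `fpar = link_a + link_b * ndvi` (with `link_b = 1 - link_a`
#' so the full FPAR range [0,1] maps into an admissible NDVI range). Means and
#' amplitudes are ordinary magnitudes for these biomes: dense evergreen
#' broadleaf forest is high and nearly aseasonal, grasslands and croplands
#' lower with a strong seasonal cycle.
#'
#' @return a data.frame with one row per vegetated biome.
#' @export
default_biome_params <- function() {
  data.frame(
    code      = unname(BIOME_CODES),
    name      = names(BIOME_CODES),
    mean_fpar = c(0.35, 0.25, 0.45, 0.40, 0.85, 0.55, 0.60, 0.45),
    amplitude = c(0.15, 0.10, 0.25, 0.15, 0.03, 0.30, 0.10, 0.25),
    phase     = c(14, 14, 14, 13, 12, 14, 13, 14),   # peak half-month period
    link_a    = c(0.04, 0.03, 0.05, 0.045, 0.08, 0.06, 0.055, 0.05),
    stringsAsFactors = FALSE)
}

#' Default mission schedule of the synthetic NDVI sensor series
#'
#' Seven consecutive eras emulating the NOAA/AVHRR platform sequence over
#' 1982-2015. `drift` is a multiplicative ramp on NDVI per year within the
#' era (orbital drift + sensor degradation); `jump` is an additive NDVI
#' offset switched in at the era boundary (platform replacement).
#'
#' @return a data.frame with one row per mission era.
#' @export
default_missions <- function() {
  data.frame(
    mission = paste0("M", 1:7),
    start   = c(1982, 1986, 1989, 1995, 2001, 2006, 2011),
    end     = c(1985, 1988, 1994, 2000, 2005, 2010, 2015),
    drift   = c(0.020, 0.025, 0.030, 0.025, 0.020, 0.015, 0.020),
    jump    = c(0.000, -0.050, 0.060, -0.060, 0.050, -0.040, 0.040),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic world
#'
#' Collects every knob of the offline input generator: grid geometry, years
#' spanned, per-biome seasonal structure and NDVI link, the per-pixel linear
#' trend, the AR(1) interannual anomaly, the sensor-artifact schedule, the
#' observation-noise levels of the two satellite records, and the master
#' seed. The defaults define a regional 60 x 120 tile at 1/12 degree over
#' 1982-2022 (24 x 41 = 984 scenes).
#'
#' @param nrow,ncol,res,lat_max,lon_min grid geometry, see [grid_spec()].
#' @param years consecutive years covered by the truth record.
#' @param biomes per-biome parameter table, see [default_biome_params()].
#' @param trend linear FPAR trend (yr^-1) applied to every pixel, or a
#'   `nrow x ncol` matrix of per-pixel trends.
#' @param ar1_sd,ar1_rho innovation sd and autocorrelation of the yearly
#'   AR(1) FPAR anomaly shared by all periods of a year.
#' @param missions mission-era table, see [default_missions()]; eras must
#'   partition `1982..ndvi_end` without gap or overlap.
#' @param ndvi_noise_sd NDVI observation noise sd.
#' @param qc_bad_frac fraction of NDVI observations flagged unusable.
#' @param benchmark_noise_sd benchmark FPAR observation noise sd.
#' @param benchmark_start first year of the benchmark record.
#' @param ndvi_end last year of the NDVI record.
#' @param splice_year first year sourced from the benchmark in the
#'   assembled product.
#' @param nonveg_frac fraction of non-vegetated cells in the biome map.
#' @param flip_frac fraction of cells whose class is re-drawn each year.
#' @param seed master seed; all generators derive their streams from it.
#' @return an object of class `world_config`.
#' @export
world_config <- function(nrow = 60, ncol = 120, res = 1 / 12,
                         lat_max = 40, lon_min = -10,
                         years = 1982:2022,
                         biomes = default_biome_params(),
                         trend = 5e-4,
                         ar1_sd = 0.01, ar1_rho = 0.3,
                         missions = default_missions(),
                         ndvi_noise_sd = 0.01,
                         qc_bad_frac = 0.05,
                         benchmark_noise_sd = 0.02,
                         benchmark_start = 2004,
                         ndvi_end = 2015,
                         splice_year = 2004,
                         nonveg_frac = 0.1,
                         flip_frac = 0.02,
                         seed = 42L) {
  grid <- grid_spec(nrow, ncol, res, lat_max, lon_min)
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  stopifnot(is.data.frame(biomes),
            all(c("code", "mean_fpar", "amplitude", "phase", "link_a") %in% names(biomes)))
  if (any(biomes$mean_fpar < 0 | biomes$mean_fpar > 1))
    stop("biome mean FPAR must lie in [0, 1]")
  span <- max(abs(trend)) * (length(years) - 1)
  worst <- pmax(biomes$mean_fpar + biomes$amplitude + span,
                1 - (biomes$mean_fpar - biomes$amplitude - span))
  if (any(worst > 1.5))
    stop("biome mean/amplitude/trend drive truth outside [0,1] by more than 0.5")
  missions <- missions[order(missions$start), ]
  ndvi_years <- years[1]:ndvi_end
  covered <- unlist(Map(seq, missions$start, missions$end))
  if (!identical(sort(covered), ndvi_years))
    stop("mission eras must partition the NDVI years without gap or overlap")
  if (!(benchmark_start %in% years) || !(ndvi_end %in% years))
    stop("benchmark_start and ndvi_end must fall within the configured years")
  if (is.matrix(trend)) stopifnot(all(dim(trend) == c(nrow, ncol)))
  structure(list(grid = grid, years = years, biomes = biomes, trend = trend,
                 ar1_sd = ar1_sd, ar1_rho = ar1_rho, missions = missions,
                 ndvi_noise_sd = ndvi_noise_sd, qc_bad_frac = qc_bad_frac,
                 benchmark_noise_sd = benchmark_noise_sd,
                 benchmark_start = as.integer(benchmark_start),
                 ndvi_end = as.integer(ndvi_end),
                 splice_year = as.integer(splice_year),
                 nonveg_frac = nonveg_frac, flip_frac = flip_frac,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Read or write a world configuration as YAML
#'
#' @param config a `world_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `world_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$grid <- x$grid[c("nrow", "ncol", "res", "lat_max", "lon_min")]
  x$trend <- if (is.matrix(config$trend)) as.vector(config$trend) else config$trend
  x$trend_is_matrix <- is.matrix(config$trend)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  trend <- if (isTRUE(x$trend_is_matrix))
    matrix(x$trend, x$grid$nrow, x$grid$ncol) else x$trend
  world_config(nrow = x$grid$nrow, ncol = x$grid$ncol, res = x$grid$res,
               lat_max = x$grid$lat_max, lon_min = x$grid$lon_min,
               years = x$years,
               biomes = as.data.frame(x$biomes, stringsAsFactors = FALSE),
               trend = trend, ar1_sd = x$ar1_sd, ar1_rho = x$ar1_rho,
               missions = as.data.frame(x$missions, stringsAsFactors = FALSE),
               ndvi_noise_sd = x$ndvi_noise_sd, qc_bad_frac = x$qc_bad_frac,
               benchmark_noise_sd = x$benchmark_noise_sd,
               benchmark_start = x$benchmark_start, ndvi_end = x$ndvi_end,
               splice_year = x$splice_year, nonveg_frac = x$nonveg_frac,
               flip_frac = x$flip_frac, seed = x$seed)
}

#' Stable fingerprint of a configuration
#'
#' MD5 of the YAML serialization; recorded in every output sidecar so
#' artifacts can be traced to the configuration and seed that produced them.
#'
#' @param config a `world_config`.
#' @return a hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}
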