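# Shared fixture builders. Everything is generated in code at test time.

# A small world: 12 x 18 cells, full mission schedule, 1982-2022.
tiny_config <- function(...) {
  world_config(nrow = 12, ncol = 18, seed = 7L, ...)
}

# A two-era mission table over custom years (handy for jump tests).
two_eras <- function(y0, y1, split, drift = c(0, 0), jump = c(0, 0)) {
  data.frame(mission = c("A", "B"),
             start = c(y0, split), end = c(split - 1, y1),
             drift = drift, jump = jump)
}

# Build an FPAR cube directly from a (time, row, col) array.
make_cube <- function(values, years, grid = NULL, varname = "fpar") {
  if (is.null(grid)) grid <- grid_spec(dim(values)[2], dim(values)[3])
  time <- make_time_axis(years)[seq_len(dim(values)[1]), , drop = FALSE]
  raster_cube(values, time, grid, varname = varname)
}

# A uniform single-biome map.
uniform_biome <- function(grid, code = BIOME_CODES[["GRA"]]) {
  biome_map(matrix(code, grid$nrow, grid$ncol), grid)
}

# Hand-constructed reflectance patch with full control over pixel values.
manual_patch <- function(bands, qa = NULL, aop = 0.1, sensor = "TM",
                         year = 2010L, period = 14L, row = 1L, col = 1L,
                         lat = 39.9, lon = -9.9) {
  if (length(dim(bands)) == 2L) bands <- array(rep(bands, 6), c(dim(bands), 6))
  dimnames(bands) <- list(NULL, NULL, c("blue", "green", "red", "nir",
                                        "swir1", "swir2"))
  if (is.null(qa)) qa <- matrix(TRUE, dim(bands)[1], dim(bands)[2])
  structure(list(bands = bands, qa = qa, aop = aop,
                 solar_zenith = 30, solar_azimuth = 120, view_zenith = 3,
                 sensor = sensor, year = year, period = period,
                 row = row, col = col, lat = lat, lon = lon),
            class = "landsat_patch")
}

# Synthetic reference pairs with a noiseless monotone target over the
# 14 forest features.
forest_pairs <- function(n, biome = 5L, sensor = "ETM+", seed = 1) {
  set.seed(seed)
  df <- data.frame(blue = runif(n, 0, 0.1), green = runif(n, 0, 0.15),
                   red = runif(n, 0, 0.2), nir = runif(n, 0.1, 0.5),
                   swir1 = runif(n, 0.05, 0.3), swir2 = runif(n, 0.05, 0.25),
                   lat = runif(n, 35, 40), lon = runif(n, -10, 0),
                   solar_zenith = runif(n, 20, 60),
                   view_zenith = runif(n, 0, 8))
  vi <- t(apply(df[, 1:6], 1, function(r)
    vegetation_indices(c(blue = r[[1]], green = r[[2]], red = r[[3]],
                         nir = r[[4]], swir1 = r[[5]], swir2 = r[[6]]))))
  df <- cbind(df, vi)
  df$fpar <- plogis(4 * df$ndvi + 2 * (df$nir - df$red) - 1)
  df$sensor <- sensor
  df$biome <- biome
  df
}

# A small world whose benchmark is a known distortion of the solely record
# over a 24 x 12-scene overlap (2004-2015).
distortion_fixture <- function(distort, noise_sd = 0, seed = 3,
                               nrow = 6, ncol = 8) {
  cfg <- world_config(nrow = nrow, ncol = ncol, years = 2000:2022,
                      benchmark_start = 2004, ndvi_end = 2015,
                      splice_year = 2004, nonveg_frac = 0, flip_frac = 0,
                      ar1_sd = 0.005, seed = seed,
                      missions = data.frame(mission = "A", start = 2000,
                                            end = 2015, drift = 0, jump = 0))
  bm <- generate_biome_map(cfg, 2010)
  truth <- generate_truth_fpar(bm, cfg)
  solely <- cube_subset_time(truth, years = 2000:2015)
  set.seed(seed)
  bvals <- distort(truth$values) + rnorm(length(truth$values), sd = noise_sd)
  bench <- raster_cube(array(pmin(pmax(bvals, 0), 1), dim(truth$values)),
                       truth$time, truth$grid)
  list(cfg = cfg, bm = bm, truth = truth, solely = solely, bench = bench)
}

# Cache for expensive end-to-end runs shared across test files.
.fixture_env <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (is.null(.fixture_env$world)) {
    cfg <- world_config(nrow = 20, ncol = 40, seed = 101L)
    .fixture_env$world <- suppressWarnings(
      run_pipeline(cfg, stages = "all", verbose = FALSE))
  }
  .fixture_env$world
}

# The same pipeline through integration with artifact amplitudes zeroed:
# the no-artifact baseline for the drift diagnostics.
baseline_world <- function() {
  if (is.null(.fixture_env$baseline)) {
    m <- default_missions()
    m$drift <- 0; m$jump <- 0
    cfg <- world_config(nrow = 20, ncol = 40, seed = 101L, missions = m)
    .fixture_env$baseline <- suppressWarnings(
      run_pipeline(cfg, stages = "integrate", verbose = FALSE))
  }
  .fixture_env$baseline
}
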