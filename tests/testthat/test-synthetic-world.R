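test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_config()
  bm1 <- generate_biome_map(cfg, 2010)
  bm2 <- generate_biome_map(cfg, 2010)
  expect_identical(bm1$codes, bm2$codes)
  tr1 <- generate_truth_fpar(bm1, cfg)
  tr2 <- generate_truth_fpar(bm1, cfg)
  expect_identical(tr1$values, tr2$values)
  nd1 <- simulate_sensor_ndvi(tr1, bm1, cfg)
  nd2 <- simulate_sensor_ndvi(tr1, bm1, cfg)
  expect_identical(nd1$values, nd2$values)
  expect_identical(nd1$qc, nd2$qc)
  b1 <- simulate_si_fpar(tr1, cfg, biome = bm1)
  b2 <- simulate_si_fpar(tr1, cfg, biome = bm1)
  expect_identical(b1$values, b2$values)
})

test_that("generated values respect physical ranges", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  v <- tr$values[!is.na(tr$values)]
  expect_true(all(v >= 0 & v <= 1))
  nd <- simulate_sensor_ndvi(tr, bm, cfg)
  n <- nd$values[!is.na(nd$values)]
  expect_true(all(n >= -1 & n <= 1))
  be <- simulate_si_fpar(tr, cfg, biome = bm)
  b <- be$values[!is.na(be$values)]
  expect_true(all(b >= 0 & b <= 1))
})

test_that("degenerate configs give analytically known truth", {
  one <- default_biome_params()[1, ]               # GRA only
  cfg <- tiny_config(biomes = one, nonveg_frac = 0, flip_frac = 0,
                     trend = 0, ar1_sd = 0)
  cfg$biomes$amplitude <- 0
  bm <- generate_biome_map(cfg, 1990)
  expect_true(all(bm$codes == BIOME_CODES[["GRA"]]))
  tr <- generate_truth_fpar(bm, cfg)
  expect_equal(max(abs(tr$values - one$mean_fpar)), 0, tolerance = 1e-12)
})

test_that("seasonal harmonic integrates to zero over the 24-period year", {
  cfg <- tiny_config(trend = 0, ar1_sd = 0, nonveg_frac = 0, flip_frac = 0)
  bm <- generate_biome_map(cfg, 1990)
  tr <- generate_truth_fpar(bm, cfg)
  means <- apply(tr$values[tr$time$year == 1990, , ], c(2, 3), mean)
  expected <- matrix(cfg$biomes$mean_fpar[match(bm$codes, cfg$biomes$code)],
                     cfg$grid$nrow)
  expect_equal(means, expected, tolerance = 1e-12)
})

test_that("a noiseless linear trend is recovered exactly by per-pixel OLS", {
  cfg <- tiny_config(trend = 0.001, ar1_sd = 0, nonveg_frac = 0)
  bm <- generate_biome_map(cfg, 1990)
  tr <- generate_truth_fpar(bm, cfg)
  # closed-form OLS oracle on the annual means of a few pixels
  years <- sort(unique(tr$time$year))
  for (px in list(c(3, 4), c(7, 11), c(12, 18))) {
    am <- vapply(years, function(y)
      mean(tr$values[tr$time$year == y, px[1], px[2]]), numeric(1))
    slope <- stats::cov(years, am) / stats::var(years)
    expect_equal(slope, 0.001, tolerance = 1e-10)
  }
})

test_that("the per-cell modal class over a flipped stack recovers the base map", {
  cfg <- tiny_config(flip_frac = 0.05)
  base_cfg <- tiny_config(flip_frac = 0)
  base <- generate_biome_map(base_cfg, 2000)
  maps <- lapply(2001:2020, generate_biome_map, config = cfg)
  stack <- vapply(maps, function(m) as.vector(m$codes),
                  integer(length(base$codes)))
  # brute-force per-cell mode
  mode_of <- apply(stack, 1, function(v) {
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)])
  })
  expect_gt(mean(mode_of == as.vector(base$codes)), 0.95)
})

test_that("an injected era-boundary jump is recoverable from era means", {
  one <- default_biome_params()[1, ]
  one$amplitude <- 0
  cfg <- tiny_config(years = 1982:2000, biomes = one, trend = 0, ar1_sd = 0,
                     nonveg_frac = 0, flip_frac = 0, qc_bad_frac = 0,
                     ndvi_noise_sd = 0.005, ndvi_end = 1999,
                     benchmark_start = 1990, splice_year = 1990,
                     missions = two_eras(1982, 1999, 1991,
                                         jump = c(0, 0.05)))
  bm <- generate_biome_map(cfg, 1990)
  tr <- generate_truth_fpar(bm, cfg)
  nd <- simulate_sensor_ndvi(tr, bm, cfg, artifacts = TRUE)
  s <- nd$values[, 5, 5]
  eraA <- nd$time$year <= 1990
  n <- min(sum(eraA), sum(!eraA))
  jump_est <- mean(s[!eraA]) - mean(s[eraA])
  expect_lt(abs(jump_est - 0.05), 4 * 0.005 / sqrt(n))
})

test_that("the QC-bad fraction matches its configured rate", {
  cfg <- tiny_config(qc_bad_frac = 0.3)
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  nd <- simulate_sensor_ndvi(tr, bm, cfg)
  veg <- !is.na(nd$values)
  frac <- mean(nd$qc[veg] == 2L)
  n <- sum(veg)
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("the benchmark equals truth when noise and spikes are off", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  be <- simulate_si_fpar(tr, cfg, noise_sd = 0, spike_frac = 0)
  expect_equal(be$values,
               cube_subset_time(tr, years = 2004:2022)$values)
})

test_that("injected benchmark spikes fall more than 3 sigma below the series mean", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  be <- simulate_si_fpar(tr, cfg, biome = bm, spike_frac = 0.005,
                         spike_mag = 0.3)
  spikes <- attr(be, "spikes")
  expect_gt(nrow(spikes), 0)
  hits <- 0
  for (i in seq_len(nrow(spikes))) {
    s <- be$values[, spikes$row[i], spikes$col[i]]
    thr <- mean(s, na.rm = TRUE) - 3 * sd(s, na.rm = TRUE)
    if (!is.na(s[spikes$t[i]]) && s[spikes$t[i]] < thr) hits <- hits + 1
  }
  expect_gt(hits / nrow(spikes), 0.9)
})

test_that("patch texture is controlled by the heterogeneity parameter", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  loc <- data.frame(lat = 39.8, lon = -9.8, year = 2010L, period = 14L)
  p0 <- simulate_landsat_patches(tr, loc, cfg, heterogeneity = 0,
                                 qa_bad_frac = 0, seed = 3L)[[1]]
  cv0 <- homogeneity_cv_filter(p0)$cv
  expect_equal(unname(cv0), rep(0, 6), tolerance = 1e-12)
  # mean CV strictly increases with heterogeneity
  levels <- c(0.01, 0.03, 0.05, 0.1, 0.2)
  cvs <- vapply(levels, function(h) {
    ps <- simulate_landsat_patches(tr, loc[rep(1, 20), ], cfg,
                                   heterogeneity = h, qa_bad_frac = 0,
                                   seed = 11L)
    mean(vapply(ps, function(p) homogeneity_cv_filter(p, cv_max = Inf)$mean_cv,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("patch-mean NDVI is monotone in the local truth FPAR", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  latc <- lat_centers(cfg$grid); lonc <- lon_centers(cfg$grid)
  set.seed(4)
  idx <- cbind(sample(cfg$grid$nrow, 40, TRUE), sample(cfg$grid$ncol, 40, TRUE))
  locs <- data.frame(lat = latc[idx[, 1]], lon = lonc[idx[, 2]],
                     year = 2005L, period = 14L)
  ps <- simulate_landsat_patches(tr, locs, cfg, heterogeneity = 0.02,
                                 qa_bad_frac = 0, seed = 5L)
  ndvi <- vapply(ps, function(p) {
    r <- aggregate_patch_reflectance(p)
    unname((r["nir"] - r["red"]) / (r["nir"] + r["red"]))
  }, numeric(1))
  truth_f <- vapply(ps, function(p)
    tr$values[cube_scene_index(tr, p$year, p$period), p$row, p$col],
    numeric(1))
  expect_gt(cor(ndvi, truth_f, method = "spearman"), 0.9)
})

test_that("ground sites reproduce the configured noise level", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  expect_identical(nrow(simulate_ground_sites(tr, cfg, 0)), 0L)
  g0 <- simulate_ground_sites(tr, cfg, 10, noise_sd = 0)
  pairs0 <- match_product_to_points(tr, g0)
  m0 <- regression_metrics(pairs0$product, pairs0$ground)
  expect_equal(m0$r2, 1, tolerance = 1e-12)
  expect_equal(m0$rmse, 0, tolerance = 1e-12)
  g1 <- simulate_ground_sites(tr, cfg, 30, noise_sd = 0.1, visit_frac = 0.3)
  d <- g1$fpar - tr$values[cbind(
    cube_scene_index(tr, g1$year, g1$period),
    cell_of(tr$grid, g1$lat, g1$lon)$row,
    cell_of(tr$grid, g1$lat, g1$lon)$col)]
  expect_gt(length(d), 500)
  expect_lt(abs(sqrt(mean(d^2)) - 0.1), 0.01)
})
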