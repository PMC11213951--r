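test_that("ground matching averages within a cell and half-month and drops fill", {
  g <- grid_spec(2, 2)
  vals <- array(0.5, c(2, 2, 2))
  vals[, 2, 2] <- NA
  cube <- raster_cube(vals, data.frame(year = 2010L, period = 1:2), g)
  latc <- lat_centers(g); lonc <- lon_centers(g)
  pts <- data.frame(lat = latc[1], lon = lonc[1], year = 2010L, period = 1L,
                    fpar = c(0.4, 0.6))
  out <- match_product_to_points(cube, pts)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ground, 0.5)
  expect_equal(out$n_obs, 2L)
  # a point over a fill pixel is dropped
  pts2 <- data.frame(lat = latc[2], lon = lonc[2], year = 2010L,
                     period = 1L, fpar = 0.5)
  expect_equal(nrow(match_product_to_points(cube, pts2)), 0L)
})

test_that("pair counts equal a brute-force group-by", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  g <- simulate_ground_sites(tr, cfg, 20, noise_sd = 0.05)
  out <- match_product_to_points(tr, g)
  cells <- cell_of(tr$grid, g$lat, g$lon)
  key <- paste(cells$row, cells$col, g$year, g$period)
  val <- vapply(unique(key), function(k)
    tr$values[cbind(cube_scene_index(tr, g$year[key == k][1],
                                     g$period[key == k][1]),
                    cells$row[key == k][1], cells$col[key == k][1])],
    numeric(1))
  expect_equal(nrow(out), sum(!is.na(val)))
})

test_that("de-seasonalization removes cycles and keeps trends", {
  p <- rep(1:24, 6)
  cyc <- sin(2 * pi * p / 24)
  a <- deseasonalize_series(cyc, p)
  expect_equal(max(abs(a)), 0, tolerance = 1e-12)
  t <- seq_along(p)
  y <- cyc + 0.001 * t
  a2 <- deseasonalize_series(y, p)
  slope_before <- unname(coef(lm(y ~ t))[2])
  slope_after <- unname(coef(lm(a2 ~ t))[2])
  # the raw fit is biased by the cycle; the anomalies recover the true slope
  expect_lt(abs(slope_after - 0.001), 1e-4)
  expect_lt(abs(slope_after - 0.001), abs(slope_before - 0.001))
  for (k in 1:24) expect_equal(mean(a2[p == k]), 0, tolerance = 1e-12)
})

test_that("EEMD reconstructs its input and isolates slow structure", {
  x <- seq(0, 10, length.out = 200)
  y <- 0.05 * x^3 - 0.5 * x^2 + sin(8 * x)
  dec <- eemd_decompose(y, seed = 3)
  expect_lte(ncol(dec$imfs), 8L)
  expect_equal(nrow(dec$imfs), length(y))
  rec <- rowSums(cbind(dec$imfs, dec$residual))
  bound <- 3 * 0.2 * sd(y) / sqrt(100)
  expect_lte(sqrt(mean((rec - y)^2)), bound)
  slow <- dec$residual + dec$imfs[, ncol(dec$imfs)]
  expect_gte(cor(slow, 0.05 * x^3 - 0.5 * x^2), 0.95)
  # constant input: no IMFs, residual is the input
  dc <- eemd_decompose(rep(0.4, 50), seed = 1)
  expect_equal(ncol(dc$imfs), 0L)
  expect_equal(dc$residual, rep(0.4, 50))
  # seeded determinism
  d1 <- eemd_decompose(y, seed = 9)
  d2 <- eemd_decompose(y, seed = 9)
  expect_identical(d1$imfs, d2$imfs)
})

test_that("per-mission bias trends are flat for zero bias and recover ramps", {
  time <- make_time_axis(1982:2001)
  missions <- two_eras(1982, 2001, 1992)
  zero <- data.frame(year = time$year, period = time$period, bias = 0)
  mt0 <- mission_bias_trends(zero, missions, seed = 2)
  expect_lte(max(abs(unlist(lapply(mt0$trends, `[[`, "trend")))), 0.01)
  # a ramp injected into era B alone is recovered within 25%
  ramp <- ifelse(time$year >= 1992,
                 0.1 * (time$year + time$period / 24 - 1992) / 10, 0)
  noisy <- data.frame(year = time$year, period = time$period,
                      bias = ramp + sin(2 * pi * time$period / 24) * 0.05)
  mt <- mission_bias_trends(noisy, missions, seed = 2)
  rng_b <- diff(range(mt$trends[["B"]]$trend))
  expect_lt(abs(rng_b - 0.1), 0.025)
  expect_equal(nrow(mt$jumps), 1L)
  # eras with no scenes produce no output and no crash
  late <- data.frame(year = 2030:2040, period = 1, bias = 0.1)
  expect_silent(out <- suppressWarnings(
    mission_bias_trends(late, missions, seed = 1)))
  expect_equal(length(out$trends), 0L)
})

test_that("gridded comparison keeps common samples, min counts and MAE winners", {
  g <- grid_spec(48, 48, res = 1 / 12, lat_max = 40, lon_min = 0)
  vals <- array(runif(48 * 48), c(1, 48, 48))
  time <- data.frame(year = 2010L, period = 14L)
  a <- raster_cube(vals, time, g)
  b <- raster_cube(array(pmin(vals + 0.1, 1), dim(vals)), time, g)
  idx <- expand.grid(row = 1:48, col = 1:48)
  refs <- data.frame(idx,
                     lat = lat_centers(g)[idx$row], lon = lon_centers(g)[idx$col],
                     year = 2010L, period = 14L,
                     fpar = vals[cbind(1L, idx$row, idx$col)])
  out <- gridded_comparison(list(A = a, B = b), refs, cell_deg = 2,
                            min_n = 100)
  expect_gt(nrow(out), 0)
  expect_true(all(out$best[out$product == "A"]))
  expect_false(any(out$best[out$product == "B"]))
  # per-cell MAE equals the brute-force mean absolute difference
  cellkey <- paste(floor(refs$lat / 2), floor(refs$lon / 2))
  for (cl in unique(out$cell)) {
    sel <- cellkey == cl
    expect_equal(out$mae[out$cell == cl & out$product == "B"],
                 mean(abs(pmin(refs$fpar[sel] + 0.1, 1) - refs$fpar[sel])),
                 tolerance = 1e-12)
  }
  # a cell with fewer than min_n samples is omitted
  out99 <- gridded_comparison(list(A = a), refs[1:99, ], cell_deg = 2,
                              min_n = 100)
  expect_equal(nrow(out99), 0L)
})

test_that("global means are cosine-area-weighted over unmasked pixels", {
  g <- grid_spec(2, 2)
  cube <- raster_cube(array(0.5, c(24, 2, 2)), make_time_axis(2000), g)
  am <- annual_and_global_means(cube)
  expect_equal(am$global$fpar, 0.5)
  # two latitudes, 0 and 60 degrees: (1 * 0.4 + 0.5 * 0.8) / 1.5
  g2 <- grid_spec(2, 1, res = 60, lat_max = 90)
  vals <- array(0, c(24, 2, 1))
  vals[, 1, 1] <- 0.8          # center at 60 N
  vals[, 2, 1] <- 0.4          # center at 0
  cube2 <- raster_cube(vals, make_time_axis(2000), g2)
  am2 <- annual_and_global_means(cube2)
  expect_equal(am2$global$fpar, (1 * 0.4 + 0.5 * 0.8) / 1.5,
               tolerance = 1e-12)
  # everything below the mask threshold leaves the mean undefined
  low <- raster_cube(array(0.04, c(24, 2, 2)), make_time_axis(2000), g)
  expect_true(is.na(annual_and_global_means(low)$global$fpar))
})

test_that("the global-mean operator is invariant to longitude relabeling", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  am <- annual_and_global_means(tr)
  perm <- sample(cfg$grid$ncol)
  tr2 <- raster_cube(tr$values[, , perm], tr$time, tr$grid)
  am2 <- annual_and_global_means(tr2)
  expect_equal(am$global$fpar, am2$global$fpar, tolerance = 1e-12)
})

test_that("Mann-Kendall statistics match first principles", {
  up <- mann_kendall_trend(1:10)
  expect_equal(up$S, 45)
  expect_gt(up$slope, 0)
  down <- mann_kendall_trend(10:1)
  expect_equal(down$S, -45)
  expect_lt(down$slope, 0)
  flat <- mann_kendall_trend(rep(1, 8))
  expect_equal(flat$S, 0)
  expect_equal(flat$p, 1)
  # cross-check p against the tie-free normal approximation of cor.test
  set.seed(8)
  y <- rnorm(30)
  ours <- mann_kendall_trend(y)
  ct <- suppressWarnings(cor.test(seq_along(y), y, method = "kendall",
                                  exact = FALSE, continuity = TRUE))
  expect_equal(ours$p, unname(ct$p.value), tolerance = 1e-10)
})

test_that("the decadal trend passes linear-limit and noise-suppression checks", {
  y <- seq(0.3, 0.4, length.out = 35)
  tr <- decadal_nonlinear_trend(y, seed = 2)
  expect_equal(length(tr), 35L)
  expect_lte(sqrt(mean((tr - y)^2)), 0.05 * diff(range(y)))
  set.seed(5)
  ratios <- vapply(1:10, function(i) {
    wn <- rnorm(35)
    var(decadal_nonlinear_trend(wn, seed = i)) / var(wn)
  }, numeric(1))
  expect_lt(mean(ratios), 0.25)
})

test_that("interannual variability follows its definitions", {
  lin <- seq(0.2, 0.6, length.out = 20)
  expect_equal(interannual_variability(lin), 0, tolerance = 1e-12)
  alt <- 0.5 + 0.05 * rep(c(-1, 1), 20)
  cfgv <- sd(alt) / mean(alt)
  # pixel-level CV on a constant-mean alternating series
  g <- grid_spec(1, 1)
  nyr <- 40
  vals <- array(rep(alt, each = 24), c(24 * nyr, 1, 1))
  cube <- raster_cube(vals, make_time_axis(2000 + seq_len(nyr) - 1), g)
  cv <- interannual_variability(cube)
  expect_equal(cv[1, 1], cfgv, tolerance = 0.02)
  expect_equal(cv[1, 1], 0.1, tolerance = 0.02)
})

test_that("Hovmoller band means match a brute-force masked mean", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- cube_subset_time(generate_truth_fpar(bm, cfg), years = 1990)
  hov <- hovmoller_means(tr, band_deg = 0.5, biome = bm)
  expect_equal(dim(hov)[2], 24L)
  latc <- lat_centers(cfg$grid)
  band <- floor((cfg$grid$lat_max - latc) / 0.5)
  for (t in c(1, 12)) {
    v <- tr$values[t, , ]
    v[bm$codes == 0L] <- NA
    for (bi in seq_along(sort(unique(band)))) {
      rows <- band == sort(unique(band))[bi]
      expect_equal(unname(hov[bi, t]),
                   mean(v[rows, , drop = FALSE], na.rm = TRUE),
                   tolerance = 1e-12)
    }
  }
  const <- raster_cube(array(0.3, c(24, cfg$grid$nrow, cfg$grid$ncol)),
                       make_time_axis(2000), cfg$grid)
  hc <- hovmoller_means(const, band_deg = 1)
  expect_true(all(abs(hc - 0.3) < 1e-12))
})
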