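test_that("negative-outlier flagging follows the one-sided three-sigma rule", {
  expect_equal(flag_negative_outliers(rep(0.8, 20)), rep(1, 20))
  # fixture with one low point; oracle = direct mean - 3 sd computation
  set.seed(1)
  s <- rnorm(100, 0.8, 0.01)
  s[40] <- 0.4
  thr <- mean(s) - 3 * sd(s)
  expect_lt(s[40], thr)
  w <- flag_negative_outliers(s)
  expect_equal(which(w == 0.1), 40L)
  # a symmetric high excursion is never flagged
  s2 <- rnorm(100, 0.5, 0.01)
  s2[10] <- 0.5 + 10 * 0.01
  expect_equal(flag_negative_outliers(s2), rep(1, 100))
  # fill points get zero weight and are excluded from the statistics
  s3 <- c(rep(0.5, 30), NA, 0.1)
  w3 <- flag_negative_outliers(s3)
  expect_equal(w3[31], 0)
  expect_equal(w3[32], 0.1)
  expect_warning(flag_negative_outliers(rep(NA_real_, 5)), "all-fill")
})

test_that("the weighted Savitzky-Golay filter reproduces polynomials exactly", {
  t <- 1:41
  cubic <- 1e-3 * t^3 - 0.05 * t^2 + 0.3 * t + 2
  out <- weighted_savgol(cubic, window_len = 7, poly_order = 3)
  expect_equal(out, cubic, tolerance = 1e-10)
  const <- rep(0.4, 30)
  w <- c(rep(1, 15), rep(0.1, 15))
  expect_equal(weighted_savgol(const, w), const, tolerance = 1e-12)
})

test_that("weighted Savitzky-Golay matches a brute-force weighted fit per window", {
  # independent oracle: lm with weights on each (shrunken) window
  oracle <- function(y, w, wl, ord) {
    n <- length(y); h <- (wl - 1) / 2
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.na(y[i])) next
      hi <- min(h, i - 1, n - i)
      idx <- (i - hi):(i + hi)
      use <- w[idx] > 0 & !is.na(y[idx])
      d <- min(ord, sum(use) - 1)
      df <- data.frame(y = y[idx][use], x = (idx - i)[use])
      fit <- lm(y ~ poly(x, degree = max(1, d), raw = TRUE), data = df,
                weights = w[idx][use])
      out[i] <- predict(fit, newdata = data.frame(x = 0))
    }
    out
  }
  set.seed(42)
  for (rep in 1:10) {
    y <- runif(40, 0.1, 0.9)
    w <- sample(c(0.1, 1), 40, replace = TRUE)
    expect_equal(weighted_savgol(y, w, 7, 2), oracle(y, w, 7, 2),
                 tolerance = 1e-10)
  }
})

test_that("unit-weight filtering agrees with the classical coefficient table", {
  skip_if_not_installed("signal")
  set.seed(3)
  y <- runif(60, 0, 1)
  ours <- weighted_savgol(y, window_len = 7, poly_order = 2)
  classical <- signal::sgolayfilt(y, p = 2, n = 7)
  interior <- 4:57
  expect_equal(ours[interior], classical[interior], tolerance = 1e-8)
})

test_that("smoothing never changes the fill status of a point", {
  set.seed(9)
  y <- runif(30)
  y[c(4, 17, 18)] <- NA
  out <- weighted_savgol(y, window_len = 5, poly_order = 2)
  expect_identical(is.na(out), is.na(y))
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  be <- simulate_si_fpar(tr, cfg, biome = bm)
  sm <- savgol_cube(cube_subset_time(be, years = 2004:2006))
  expect_identical(is.na(sm$values),
                   is.na(cube_subset_time(be, years = 2004:2006)$values))
})

test_that("savgol_cube agrees with the per-series filter on flagged pixels", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  tr <- generate_truth_fpar(bm, cfg)
  be <- simulate_si_fpar(tr, cfg, biome = bm, spike_frac = 0.02)
  sub <- cube_subset_time(be, years = 2004:2008)
  sm <- savgol_cube(sub)
  spikes <- attr(be, "spikes")
  px <- unique(spikes[spikes$t <= dim(sub$values)[1], c("row", "col")])[1:5, ]
  for (i in seq_len(nrow(px))) {
    y <- sub$values[, px$row[i], px$col[i]]
    w <- flag_negative_outliers(y)
    expect_equal(sm$values[, px$row[i], px$col[i]],
                 pmin(pmax(weighted_savgol(y, w), 0), 1), tolerance = 1e-10)
  }
})

test_that("maximum value composite takes the per-pixel max over valid values", {
  expect_equal(max_value_composite(0.37), 0.37)
  expect_equal(max_value_composite(c(0.2, 0.5, NA)), 0.5)
  expect_true(is.na(max_value_composite(c(NA_real_, NA_real_))))
  m <- rbind(c(0.1, NA), c(0.7, 0.2), c(0.3, NA))
  expect_equal(max_value_composite(m), c(0.7, 0.2))
})

test_that("8-day observations composite onto the half-month calendar", {
  dates <- seq(as.Date("2005-01-01"), as.Date("2005-12-31"), by = 8)
  vals <- seq_along(dates) / length(dates)
  out <- composite_to_halfmonth(vals, dates)
  expect_equal(nrow(out$time), length(unique(paste(
    format(dates, "%m"), as.integer(format(dates, "%d")) <= 15))))
  # calendar oracle: period = 2 * month - (day <= 15)
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  oracle_period <- 2L * m - (d <= 15L)
  for (k in seq_len(nrow(out$time))) {
    members <- which(oracle_period == out$time$period[k])
    expect_equal(out$values[k, 1], max(vals[members]))
  }
})

test_that("regridding preserves constants and reproduces linear ramps", {
  const <- matrix(0.6, 8, 10)
  expect_equal(regrid_matrix(const, c(16, 20), "bicubic"),
               matrix(0.6, 16, 20), tolerance = 1e-12)
  expect_equal(regrid_matrix(const, c(3, 5), "nearest"), matrix(0.6, 3, 5))
  # analytic bilinear ramp oracle at the target cell centers
  f <- function(u, v) 2 * u + 3 * v
  src <- outer(1:10, 1:20, f)
  got <- regrid_matrix(src, c(25, 50), "bicubic")
  u <- (1:25 - 0.5) * 10 / 25 + 0.5
  v <- (1:50 - 0.5) * 20 / 50 + 0.5
  expect_equal(got, outer(u, v, f), tolerance = 1e-6)
})

test_that("categorical resampling emits only input classes and fill propagates", {
  cfg <- tiny_config()
  bm <- generate_biome_map(cfg, 2000)
  shr <- regrid(bm, c(6, 9))
  expect_true(all(shr$codes %in% bm$codes))
  src <- matrix(runif(100), 10, 10)
  src[5, 5] <- NA
  out <- regrid_matrix(src, c(10, 10), "bicubic")
  expect_true(any(is.na(out)))
  expect_error(regrid_matrix(src, c(5, 5), "sinc"))
})

test_that("the majority map takes the per-cell mode with earliest-year ties", {
  g <- grid_spec(2, 2)
  mk <- function(v, yr) biome_map(matrix(v, 2, 2), g, year = yr)
  same <- replicate(5, mk(c(1, 2, 3, 4), 2000), simplify = FALSE)
  expect_equal(majority_biome_map(same)$codes, matrix(c(1, 2, 3, 4), 2, 2))
  # 12 x GRA vs 8 x SAV -> GRA
  maps <- c(replicate(12, mk(1, 2000), simplify = FALSE),
            replicate(8, mk(4, 2012), simplify = FALSE))
  expect_true(all(majority_biome_map(maps)$codes == 1L))
  # 10 x 10 tie -> the class of the earliest year (SAV listed first here)
  maps2 <- c(replicate(10, mk(4, 2000), simplify = FALSE),
             replicate(10, mk(1, 2010), simplify = FALSE))
  expect_true(all(majority_biome_map(maps2)$codes == 4L))
  g2 <- grid_spec(3, 3)
  expect_error(majority_biome_map(list(mk(1, 2000),
                                       biome_map(matrix(1, 3, 3), g2))),
               "mismatched")
})

test_that("low-FPAR masking is strictly below the threshold", {
  vals <- array(c(0.04, 0.05, 0.5, 0.2), c(1, 2, 2))
  cube <- make_cube(vals, 2000)
  m0 <- mask_low_fpar(cube, 0)
  expect_equal(m0$values, cube$values)
  m <- mask_low_fpar(cube, 0.05)
  expect_true(is.na(m$values[1, 1, 1]))
  expect_equal(m$values[1, 2, 1], 0.05)
  # masked count equals the brute-force count
  set.seed(2)
  big <- make_cube(array(runif(240), c(10, 4, 6)), 2000)
  masked <- mask_low_fpar(big, 0.05)
  expect_equal(sum(is.na(masked$values)), sum(big$values < 0.05))
})
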