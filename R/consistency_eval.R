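#' Match a product to ground measurements
#'
#' Ground values are averaged within identical spatial (grid cell) and
#' temporal (half-month) frames, then paired with the product value of that
#' cell and scene; pairs over fill are dropped.
#'
#' @param product an FPAR `raster_cube`.
#' @param points data.frame of measurements with `lat`, `lon`, `year`,
#'   `period`, `fpar` (e.g. from [simulate_ground_sites()]).
#' @return data.frame of pairs: `row`, `col`, `year`, `period`,
#'   `ground`, `product`, `n_obs`.
#' @export
match_product_to_points <- function(product, points) {
  if (!nrow(points))
    return(data.frame(row = integer(0), col = integer(0), year = integer(0),
                      period = integer(0), ground = numeric(0),
                      product = numeric(0), n_obs = integer(0)))
  cells <- cell_of(product$grid, points$lat, points$lon)
  keep <- !is.na(cells$row)
  pts <- cbind(points[keep, ], cells[keep, ])
  key <- paste(pts$row, pts$col, pts$year, pts$period)
  agg <- stats::aggregate(pts$fpar, by = list(key = key), FUN = mean)
  cnt <- table(key)
  meta <- pts[!duplicated(key), c("row", "col", "year", "period")]
  meta <- meta[match(agg$key, paste(meta$row, meta$col, meta$year, meta$period)), ]
  ti <- cube_scene_index(product, meta$year, meta$period)
  prod_v <- rep(NA_real_, nrow(meta))
  ok <- !is.na(ti)
  prod_v[ok] <- product$values[cbind(ti[ok], meta$row[ok], meta$col[ok])]
  out <- data.frame(meta, ground = agg$x, product = prod_v,
                    n_obs = as.integer(cnt[agg$key]))
  out <- out[!is.na(out$product), ]
  rownames(out) <- NULL
  out
}

#' De-seasonalize a half-monthly series
#'
#' Subtracts the multi-year climatological mean of each half-month period.
#' Periods with no data stay missing.
#'
#' @param x numeric series.
#' @param period integer periods (1..24) aligned to `x`.
#' @return anomaly series of the same length.
#' @export
deseasonalize_series <- function(x, period) {
  stopifnot(length(x) == length(period))
  clim <- tapply(x, period, mean, na.rm = TRUE)
  x - as.numeric(clim[as.character(period)])
}

#' Global-mean bias series between a product and a reference cube
#'
#' Per scene, the mean of (product - reference) over pixels valid in both.
#'
#' @param product,reference co-registered FPAR `raster_cube`s (time axes
#'   intersected by scene stamp).
#' @return data.frame: `year`, `period`, `bias`, `n` (pixels used).
#' @export
global_bias_series <- function(product, reference) {
  kp <- paste(product$time$year, product$time$period)
  kr <- paste(reference$time$year, reference$time$period)
  common <- intersect(kp, kr)
  out <- data.frame(year = as.integer(sub(" .*", "", common)),
                    period = as.integer(sub(".* ", "", common)),
                    bias = NA_real_, n = 0L)
  for (i in seq_along(common)) {
    d <- product$values[match(common[i], kp), , ] -
      reference$values[match(common[i], kr), , ]
    out$bias[i] <- mean(d, na.rm = TRUE)
    out$n[i] <- sum(!is.na(d))
  }
  out
}

#' Per-mission nonlinear trends of a de-seasonalized bias series
#'
#' Splits the scene-wise bias series by mission era, de-seasonalizes it,
#' and extracts each era's nonlinear trend by ensemble empirical mode
#' decomposition: the trend is the EEMD residual, with the last IMF added
#' for eras of at least `long_era_years` years (slow modes leak into the
#' last IMF on long records). The era-boundary jump statistic is the
#' difference between the trend endpoint of one era and the trend start
#' point of the next.
#'
#' @param bias data.frame from [global_bias_series()] (columns `year`,
#'   `period`, `bias`).
#' @param missions mission-era table with `mission`, `start`, `end`.
#' @param long_era_years era length (years) from which the last IMF is
#'   included in the trend (default 8; set `Inf` for residual-only).
#' @param noise_level,ensemble,max_imfs,seed EEMD settings.
#' @return list with `trends` (named list of per-era data.frames: `year`,
#'   `period`, `bias`, `trend`) and `jumps` (data.frame of boundary jump
#'   statistics).
#' @export
mission_bias_trends <- function(bias, missions, long_era_years = 8,
                                noise_level = 0.2, ensemble = 100L,
                                max_imfs = 8L, seed = 1L) {
  anom <- deseasonalize_series(bias$bias, bias$period)
  trends <- list()
  for (e in seq_len(nrow(missions))) {
    m <- missions[e, ]
    sel <- which(bias$year >= m$start & bias$year <= m$end & !is.na(anom))
    if (!length(sel)) next
    span <- diff(range(bias$year[sel])) + 1
    if (span < 2) {
      warning(sprintf("era %s shorter than 2 years: skipped", m$mission))
      next
    }
    dec <- eemd_decompose(anom[sel], noise_level = noise_level,
                          ensemble = ensemble, max_imfs = max_imfs,
                          seed = seed + e)
    trend <- dec$residual
    if (span >= long_era_years && ncol(dec$imfs) > 0)
      trend <- trend + dec$imfs[, ncol(dec$imfs)]
    trends[[m$mission]] <- data.frame(year = bias$year[sel],
                                      period = bias$period[sel],
                                      bias = anom[sel], trend = trend)
  }
  jumps <- NULL
  nm <- names(trends)
  if (length(trends) >= 2)
    jumps <- data.frame(
      boundary = paste(nm[-length(nm)], nm[-1], sep = "->"),
      jump = vapply(seq_len(length(trends) - 1), function(i) {
        a <- trends[[i]]$trend; b <- trends[[i + 1]]$trend
        b[1] - a[length(a)]
      }, numeric(1)))
  list(trends = trends, jumps = jumps)
}

#' Gridded product comparison against reference samples
#'
#' Restricts to samples valid in every product, bins them into square
#' latitude-longitude cells, and per cell and product computes MAE, RMSE
#' and the correlation R against the reference; cells with fewer than
#' `min_n` common samples are omitted. The best product per cell minimizes
#' MAE (ties go to the first product in list order).
#'
#' @param products named list of FPAR `raster_cube`s.
#' @param refs reference samples with `row`, `col`, `lat`, `lon`, `year`,
#'   `period`, `fpar`.
#' @param cell_deg comparison cell size in degrees (default 2).
#' @param min_n minimum common samples per retained cell (default 100).
#' @return data.frame: one row per (cell, product) with metrics, plus the
#'   per-cell `best` flag.
#' @export
gridded_comparison <- function(products, refs, cell_deg = 2, min_n = 100L) {
  stopifnot(length(products) >= 1, !is.null(names(products)))
  if (!nrow(refs)) return(data.frame())
  vals <- sapply(products, function(pr) {
    ti <- cube_scene_index(pr, refs$year, refs$period)
    v <- rep(NA_real_, nrow(refs))
    ok <- !is.na(ti)
    v[ok] <- pr$values[cbind(ti[ok], refs$row[ok], refs$col[ok])]
    v
  })
  vals <- matrix(vals, nrow = nrow(refs),
                 dimnames = list(NULL, names(products)))
  common <- stats::complete.cases(vals) & !is.na(refs$fpar)
  refs <- refs[common, , drop = FALSE]
  vals <- vals[common, , drop = FALSE]
  cell <- paste(floor(refs$lat / cell_deg), floor(refs$lon / cell_deg))
  rows <- list()
  for (cl in unique(cell)) {
    sel <- cell == cl
    if (sum(sel) < min_n) next
    mets <- lapply(names(products), function(pn) {
      err <- vals[sel, pn] - refs$fpar[sel]
      data.frame(cell = cl, product = pn,
                 mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 r = suppressWarnings(stats::cor(vals[sel, pn], refs$fpar[sel])),
                 n = sum(sel))
    })
    mets <- do.call(rbind, mets)
    mets$best <- seq_len(nrow(mets)) == which.min(mets$mae)
    rows[[cl]] <- mets
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annual mean grids and the area-weighted global mean series
#'
#' Masks FPAR below the threshold, averages each pixel over the scenes of
#' each year, and reduces each annual grid to a global mean weighted by the
#' cosine of the pixel-center latitude over vegetated, unmasked pixels.
#'
#' @param cube an FPAR `raster_cube` (full years).
#' @param biome optional [biome_map()]; restricts to vegetated cells.
#' @param min_fpar mask threshold (strict below; default 0.05).
#' @return list with `annual` (year x row x col array), `years`, and
#'   `global` (data.frame `year`, `fpar`; NA when all pixels are masked).
#' @export
annual_and_global_means <- function(cube, biome = NULL, min_fpar = 0.05) {
  cube <- mask_low_fpar(cube, min_fpar)
  years <- sort(unique(cube$time$year))
  g <- cube$grid
  annual <- array(NA_real_, c(length(years), g$nrow, g$ncol))
  for (i in seq_along(years)) {
    sel <- cube$time$year == years[i]
    block <- cube$values[sel, , , drop = FALSE]
    cnt <- apply(!is.na(block), c(2, 3), sum)
    s <- apply(block, c(2, 3), sum, na.rm = TRUE)
    m <- s / cnt
    m[cnt == 0] <- NA_real_
    annual[i, , ] <- m
  }
  w <- matrix(rep(cos(lat_centers(g) * pi / 180), g$ncol), g$nrow)
  if (!is.null(biome)) w[biome$codes == 0L] <- 0
  global <- vapply(seq_along(years), function(i) {
    a <- annual[i, , ]
    use <- !is.na(a) & w > 0
    if (!any(use)) return(NA_real_)
    sum(a[use] * w[use]) / sum(w[use])
  }, numeric(1))
  list(annual = annual, years = years,
       global = data.frame(year = years, fpar = global))
}

#' Linear trend with Mann-Kendall significance
#'
#' The trend magnitude is the ordinary least-squares slope on the year
#' index; its significance comes from the Mann-Kendall test: the S
#' statistic over all sign pairs, tie-corrected variance, and the
#' continuity-corrected normal approximation. Sen's median slope is also
#' reported as an alternative magnitude.
#'
#' @param y numeric annual series (n >= 4; NA dropped pairwise with years).
#' @param years optional year labels (defaults to the index).
#' @return object of class `trend_result`: `slope`, `intercept`,
#'   `sen_slope`, `S`, `varS`, `z`, `p`, and significance `stars` at
#'   0.05 / 0.01 / 0.001.
#' @export
mann_kendall_trend <- function(y, years = NULL) {
  if (is.null(years)) years <- seq_along(y)
  keep <- !is.na(y)
  y <- y[keep]; years <- years[keep]
  n <- length(y)
  if (n < 4) stop("need at least 4 points")
  fit <- stats::lm.fit(cbind(1, years), y)
  pairs <- utils::combn(n, 2)
  dy <- y[pairs[2, ]] - y[pairs[1, ]]
  dx <- years[pairs[2, ]] - years[pairs[1, ]]
  S <- sum(sign(dy))
  ties <- table(y)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(varS)
       else if (S < 0) (S + 1) / sqrt(varS)
       else 0
  if (varS == 0) z <- 0
  p <- if (varS == 0) 1 else 2 * stats::pnorm(-abs(z))
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else ""
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 sen_slope = stats::median(dy / dx),
                 S = S, varS = varS, z = z, p = p, stars = stars, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("slope = %.3g yr^-1 (Sen %.3g), MK S = %d, z = %.2f, p = %.3g %s\n",
              x$slope, x$sen_slope, x$S, x$z, x$p, x$stars))
  invisible(x)
}

#' Decadal-scale nonlinear trend of an annual series
#'
#' Decomposes the series into `n_components` components by EEMD (the
#' residual counts as a component, so at most `n_components - 1` IMFs are
#' extracted) and sums the last two components. When the decomposition
#' yields fewer than two components the residual alone is returned with a
#' warning.
#'
#' @param y numeric annual series (length >= 12 advised).
#' @param n_components total component count (default 4).
#' @param noise_level,ensemble,seed EEMD settings.
#' @return numeric trend series of the same length.
#' @export
decadal_nonlinear_trend <- function(y, n_components = 4L, noise_level = 0.2,
                                    ensemble = 100L, seed = 1L) {
  dec <- eemd_decompose(y, noise_level = noise_level, ensemble = ensemble,
                        max_imfs = n_components - 1L, seed = seed)
  comp <- cbind(dec$imfs, dec$residual)
  if (ncol(comp) < 2) {
    warning("decomposition yielded fewer than 2 components: residual only")
    return(dec$residual)
  }
  rowSums(comp[, c(ncol(comp) - 1L, ncol(comp)), drop = FALSE])
}

#' Interannual variability
#'
#' For a global annual series: the standard deviation of the detrended
#' annual anomalies (detrending removes the OLS line). For a cube: the
#' per-pixel coefficient of variation of the detrended annual-mean series,
#' sd(detrended)/mean (missing where the mean is non-positive).
#'
#' @param x numeric annual series, or an FPAR `raster_cube`.
#' @param ... passed to [annual_and_global_means()] for cubes.
#' @return a scalar for series input; a matrix of CVs for cube input.
#' @export
interannual_variability <- function(x, ...) {
  detrend <- function(v) {
    t <- seq_along(v)
    keep <- !is.na(v)
    if (sum(keep) < 3) return(rep(NA_real_, length(v)))
    fit <- stats::lm.fit(cbind(1, t[keep]), v[keep])
    out <- rep(NA_real_, length(v))
    out[keep] <- fit$residuals
    out
  }
  if (inherits(x, "raster_cube")) {
    am <- annual_and_global_means(x, ...)
    g <- x$grid
    out <- matrix(NA_real_, g$nrow, g$ncol)
    for (i in seq_len(g$nrow)) for (j in seq_len(g$ncol)) {
      v <- am$annual[, i, j]
      if (sum(!is.na(v)) < 3) next
      m <- mean(v, na.rm = TRUE)
      if (!is.finite(m) || m <= 0) next
      out[i, j] <- stats::sd(detrend(v), na.rm = TRUE) / m
    }
    return(out)
  }
  stopifnot(sum(!is.na(x)) >= 3)
  stats::sd(detrend(x), na.rm = TRUE)
}

#' Latitude-time (Hovmoller) band means
#'
#' Per latitudinal band and scene, the unweighted mean over valid
#' (optionally vegetated) pixels.
#'
#' @param cube an FPAR `raster_cube`.
#' @param band_deg band height in degrees (> 0).
#' @param biome optional [biome_map()] restricting to vegetated cells.
#' @return a matrix (bands x scenes) with band-center latitudes as row
#'   names; empty bands are rows of NA.
#' @export
hovmoller_means <- function(cube, band_deg, biome = NULL) {
  stopifnot(band_deg > 0)
  g <- cube$grid
  latc <- lat_centers(g)
  band <- floor((g$lat_max - latc) / band_deg)
  bands <- sort(unique(band))
  nt <- nrow(cube$time)
  out <- matrix(NA_real_, length(bands), nt)
  rownames(out) <- sprintf("%.2f", g$lat_max - (bands + 0.5) * band_deg)
  veg <- if (is.null(biome)) matrix(TRUE, g$nrow, g$ncol) else biome$codes > 0L
  for (t in seq_len(nt)) {
    v <- cube$values[t, , ]
    v[!veg] <- NA
    for (bi in seq_along(bands)) {
      rows <- band == bands[bi]
      out[bi, t] <- mean(v[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  out
}
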