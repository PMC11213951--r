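#' Flag negative outliers in an FPAR time series
#'
#' Applies the one-sided three-sigma rule over the full multi-year series of
#' a pixel: valid points falling below `mean - 3 * sd` (mean and unweighted
#' sample sd computed over valid points only, single pass) receive weight
#' 0.1, all other valid points weight 1.0, fill points weight 0. Only the
#' negative side is flagged: cloud- and aerosol-contaminated FPAR retrievals
#' bias low, so high excursions are left untouched.
#'
#' @param series numeric vector (NA = fill).
#' @return numeric weight vector in {0, 0.1, 1} aligned to `series`.
#' @export
flag_negative_outliers <- function(series) {
  w <- rep(1, length(series))
  valid <- !is.na(series)
  w[!valid] <- 0
  if (!any(valid)) {
    warning("all-fill series: returning zero weights")
    return(w)
  }
  if (sum(valid) >= 4) {
    m <- mean(series[valid])
    s <- stats::sd(series[valid])
    if (is.finite(s) && s > 0)
      w[valid & series < m - 3 * s] <- 0.1
  }
  w
}

# Solve one weighted local polynomial fit and return the center evaluation.
wls_center <- function(y, w, tt, order) {
  use <- w > 0 & !is.na(y)
  if (!any(use)) return(NA_real_)
  ord <- min(order, sum(use) - 1L)
  X <- outer(tt[use], 0:max(0L, ord), `^`)
  sw <- sqrt(w[use])
  fit <- qr(X * sw)
  beta <- qr.coef(fit, y[use] * sw)
  beta[is.na(beta)] <- 0
  beta[1]
}

#' Weighted Savitzky-Golay filter
#'
#' Each output point is the center evaluation of the weighted least-squares
#' polynomial of order `poly_order` fitted over a window of `window_len`
#' points around it. Edges are handled by shrinking the window symmetrically;
#' fill values carry zero weight and their fill status is preserved in the
#' output. When fewer usable points than `poly_order + 1` fall in a window,
#' the polynomial order is reduced accordingly.
#'
#' @param series numeric vector (NA = fill).
#' @param weights non-negative per-point weights (e.g. from
#'   [flag_negative_outliers()]); defaults to unit weights.
#' @param window_len odd window length, must exceed `poly_order`.
#' @param poly_order polynomial order of the local fit.
#' @return smoothed numeric vector; NA exactly where `series` is NA.
#' @export
weighted_savgol <- function(series, weights = NULL, window_len = 7L,
                            poly_order = 2L) {
  n <- length(series)
  if (window_len %% 2 != 1) stop("window_len must be odd")
  if (window_len <= poly_order) stop("window_len must exceed poly_order")
  if (window_len > n) stop("window larger than series")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  weights[is.na(series)] <- 0
  h <- (window_len - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(series[i])) next
    hi <- min(h, i - 1L, n - i)
    idx <- (i - hi):(i + hi)
    v <- wls_center(series[idx], weights[idx], idx - i, poly_order)
    out[i] <- if (is.na(v)) series[i] else v
  }
  out
}

#' Apply the weighted Savitzky-Golay filter to every pixel of a cube
#'
#' Per-pixel weights come from [flag_negative_outliers()]. Pixels whose
#' series is fully valid with no down-weighted point share one precomputed
#' linear smoother (a banded matrix multiply); the remainder fall back to
#' the generic weighted fit.
#'
#' @param cube an FPAR `raster_cube`.
#' @param window_len,poly_order filter settings, see [weighted_savgol()].
#' @return a smoothed `raster_cube` (values clipped to [0, 1]).
#' @export
savgol_cube <- function(cube, window_len = 7L, poly_order = 2L) {
  nt <- dim(cube$values)[1]
  np <- prod(dim(cube$values)[2:3])
  X <- matrix(cube$values, nt, np)
  # shared smoother for unit-weight, gap-free series (includes edge rows)
  C <- matrix(0, nt, nt)
  h <- (window_len - 1L) %/% 2L
  for (i in seq_len(nt)) {
    hi <- min(h, i - 1L, nt - i)
    idx <- (i - hi):(i + hi)
    tt <- idx - i
    Xd <- outer(tt, 0:min(poly_order, length(idx) - 1L), `^`)
    C[i, idx] <- (solve(crossprod(Xd)) %*% t(Xd))[1, ]
  }
  out <- matrix(NA_real_, nt, np)
  for (p in seq_len(np)) {
    y <- X[, p]
    if (all(is.na(y))) next
    w <- suppressWarnings(flag_negative_outliers(y))
    if (!anyNA(y)) {
      out[, p] <- C %*% y
      bad <- which(w != 1)
      if (length(bad)) {
        # only windows touching a down-weighted point need a custom solve
        touch <- unique(pmin(nt, pmax(1L, rep(bad, each = 2L * h + 1L) +
                                        (-h):h)))
        for (i in touch) {
          hi <- min(h, i - 1L, nt - i)
          idx <- (i - hi):(i + hi)
          v <- wls_center(y[idx], w[idx], idx - i, poly_order)
          out[i, p] <- if (is.na(v)) y[i] else v
        }
      }
    } else {
      out[, p] <- weighted_savgol(y, w, window_len, poly_order)
    }
  }
  raster_cube(array(clip01(out), dim(cube$values)), cube$time, cube$grid,
              qc = cube$qc, varname = cube$varname)
}

#' Maximum value composite
#'
#' Per-pixel maximum over the valid observations contributing to one target
#' period; fill when no observation is valid.
#'
#' @param x numeric vector, matrix (obs in rows) or 3-d array (obs along
#'   the first dimension) of sub-period observations.
#' @return the composited value(s), same spatial shape as one observation.
#' @export
max_value_composite <- function(x) {
  if (is.null(dim(x))) {
    if (all(is.na(x))) return(NA_real_)
    return(max(x, na.rm = TRUE))
  }
  m <- if (length(dim(x)) == 3L) apply(x, c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  else apply(x, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  m
}

#' Composite dated observations to the half-month calendar
#'
#' Assigns each dated observation to its half-month period (days 1-15 /
#' 16-end) and takes the per-pixel maximum value composite within each
#' (year, period).
#'
#' @param values matrix with one row per observation (columns = pixels), or
#'   a vector for a single pixel.
#' @param dates `Date` vector aligned to the rows of `values`.
#' @return list with `values` (matrix, one row per composited scene),
#'   `time` (data.frame year/period).
#' @export
composite_to_halfmonth <- function(values, dates) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  dates <- as.Date(dates)
  stopifnot(nrow(values) == length(dates))
  year <- as.integer(format(dates, "%Y"))
  period <- half_month_of(dates)
  key <- paste(year, period)
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  out <- t(vapply(groups, function(i)
    max_value_composite(values[i, , drop = FALSE]),
    numeric(ncol(values))))
  if (ncol(values) == 1L) out <- matrix(out, ncol = 1)
  uk <- unique(key)
  ym <- do.call(rbind, strsplit(uk, " "))
  list(values = out,
       time = data.frame(year = as.integer(ym[, 1]), period = as.integer(ym[, 2])))
}

# Keys bicubic convolution kernel (a = -0.5): exact for linear fields.
keys_kernel <- function(s) {
  s <- abs(s)
  ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
         ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
}

#' Resample a matrix to a new shape
#'
#' Bicubic convolution (Keys kernel) for continuous fields, nearest
#' neighbor for categorical ones. The source and target extents coincide;
#' cell centers are half a cell inside the edges. For bicubic resampling
#' the source is padded by linear extrapolation so linear fields are
#' reproduced exactly up to the boundary, and any fill value inside a
#' target cell's 4 x 4 footprint propagates fill.
#'
#' @param x numeric matrix.
#' @param target_shape integer vector `c(nrow, ncol)` of the output.
#' @param method `"bicubic"` or `"nearest"`.
#' @return a matrix of shape `target_shape`.
#' @export
regrid_matrix <- function(x, target_shape, method = c("bicubic", "nearest")) {
  method <- match.arg(method)
  nr <- nrow(x); nc <- ncol(x)
  tr <- target_shape[1]; tc <- target_shape[2]
  # target cell centers in source index coordinates
  u <- (seq_len(tr) - 0.5) * nr / tr + 0.5
  v <- (seq_len(tc) - 0.5) * nc / tc + 0.5
  if (method == "nearest") {
    ri <- pmin(nr, pmax(1L, round(u)))
    ci <- pmin(nc, pmax(1L, round(v)))
    return(x[ri, ci, drop = FALSE])
  }
  # pad by 2 with linear extrapolation
  pad <- function(m) {
    top <- 2 * m[1, ] - m[2, ]; top2 <- 2 * top - m[1, ]
    bot <- 2 * m[nrow(m), ] - m[nrow(m) - 1, ]; bot2 <- 2 * bot - m[nrow(m), ]
    m <- rbind(top2, top, m, bot, bot2)
    left <- 2 * m[, 1] - m[, 2]; left2 <- 2 * left - m[, 1]
    right <- 2 * m[, ncol(m)] - m[, ncol(m) - 1]
    right2 <- 2 * right - m[, ncol(m)]
    cbind(left2, left, m, right, right2)
  }
  if (nr < 2 || nc < 2) {
    # degenerate source: constant extension
    xp <- matrix(x[pmin(nr, pmax(1, rep(1:nr, length.out = nr + 4) - 2)),
                   pmin(nc, pmax(1, rep(1:nc, length.out = nc + 4) - 2))],
                 nr + 4, nc + 4)
  } else xp <- pad(x)
  out <- matrix(NA_real_, tr, tc)
  for (i in seq_len(tr)) {
    m <- floor(u[i])
    ridx <- (m - 1):(m + 2)
    wr <- keys_kernel(u[i] - ridx)
    for (j in seq_len(tc)) {
      n <- floor(v[j])
      cidx <- (n - 1):(n + 2)
      wc <- keys_kernel(v[j] - cidx)
      blk <- xp[ridx + 2, cidx + 2]
      if (anyNA(blk)) next                      # fill propagates
      out[i, j] <- drop(wr %*% blk %*% wc)
    }
  }
  out
}

#' Resample grids and maps
#'
#' Dispatches [regrid_matrix()]: continuous fields are resampled
#' bicubically, categorical biome maps by nearest neighbor (so output
#' classes are a subset of input classes).
#'
#' @param x a matrix or a [biome_map()].
#' @param target_shape integer `c(nrow, ncol)`.
#' @param method `"bicubic"` or `"nearest"`; a biome map forces nearest.
#' @param grid optional `grid_spec` of the output (for biome maps).
#' @return same class as `x` at the new shape.
#' @export
regrid <- function(x, target_shape, method = c("bicubic", "nearest"),
                   grid = NULL) {
  method <- match.arg(method)
  if (inherits(x, "biome_map")) {
    codes <- regrid_matrix(x$codes, target_shape, method = "nearest")
    g <- if (is.null(grid))
      grid_spec(target_shape[1], target_shape[2],
                res = x$grid$res * x$grid$nrow / target_shape[1],
                lat_max = x$grid$lat_max, lon_min = x$grid$lon_min)
    else grid
    return(biome_map(codes, g, year = x$year))
  }
  regrid_matrix(x, target_shape, method = method)
}

#' Majority biome map over a stack of yearly maps
#'
#' Per-cell modal class over the supplied years; ties are broken in favor of
#' the class occurring in the earliest year among those tied.
#'
#' @param yearly_maps list of [biome_map()]s on the same grid, in year order.
#' @return a [biome_map()] labelled with the first year.
#' @export
majority_biome_map <- function(yearly_maps) {
  stopifnot(length(yearly_maps) >= 1)
  g <- yearly_maps[[1]]$grid
  for (m in yearly_maps)
    if (!same_grid(m$grid, g)) stop("yearly maps on mismatched grids")
  stack <- vapply(yearly_maps, function(m) as.vector(m$codes),
                  integer(g$nrow * g$ncol))
  if (is.null(dim(stack))) stack <- matrix(stack, nrow = 1)
  modal <- apply(stack, 1, function(v) {
    counts <- tabulate(v + 1L, nbins = 9L)       # classes 0..8
    best <- which(counts == max(counts)) - 1L
    if (length(best) == 1L) return(best)
    best[which.min(vapply(best, function(b) match(b, v), integer(1)))]
  })
  biome_map(matrix(as.integer(modal), g$nrow, g$ncol), g,
            year = yearly_maps[[1]]$year)
}

#' Mask low FPAR values
#'
#' Values strictly below the threshold become fill (values exactly at the
#' threshold are kept).
#'
#' @param cube an FPAR `raster_cube`.
#' @param threshold FPAR threshold in [0, 1] (default 0.05).
#' @return a `raster_cube` with low values filled.
#' @export
mask_low_fpar <- function(cube, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  v <- cube$values
  v[!is.na(v) & v < threshold] <- NA_real_
  raster_cube(v, cube$time, cube$grid, qc = cube$qc, varname = cube$varname,
              provenance = cube$provenance)
}
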