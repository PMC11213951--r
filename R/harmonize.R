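#' Fit pixel-wise overlap-period calibrations
#'
#' For every pixel, regresses the benchmark record (y) on the solely record
#' (x) over their overlap scenes. Evergreen broadleaf forest pixels get a
#' univariate penalized-spline smooth (cubic regression spline with 8 basis
#' functions, smoothing by GCV via `mgcv::gam`); every other biome gets
#' ordinary least squares. Pixels with fewer than `min_pairs` valid pairs —
#' or degenerate x variance — are flagged identity. The overlap correlation
#' R and fit RMSE are stored per pixel.
#'
#' @param solely,benchmark co-registered FPAR `raster_cube`s.
#' @param biome a [biome_map()] on the same grid.
#' @param overlap_years years of the fitting overlap (default 2004-2015).
#' @param min_pairs minimum valid pairs for a non-identity fit (default 24).
#' @param k spline basis dimension for the EBF smooth (default 8).
#' @return an object of class `pixel_calibration`: per-pixel matrices
#'   `slope`, `intercept`, `r`, `rmse`, `n`, `method` (0 identity,
#'   1 linear, 2 smooth) and the fitted smooths.
#' @export
fit_pixel_calibration <- function(solely, benchmark, biome,
                                  overlap_years = 2004:2015,
                                  min_pairs = 24L, k = 8L) {
  if (!same_grid(solely$grid, benchmark$grid)) stop("grids do not match")
  g <- solely$grid
  xs <- cube_subset_time(solely, years = overlap_years)
  ys <- cube_subset_time(benchmark, years = overlap_years)
  key_x <- paste(xs$time$year, xs$time$period)
  key_y <- paste(ys$time$year, ys$time$period)
  common <- intersect(key_x, key_y)
  if (!length(common)) stop("empty overlap period")
  X <- matrix(xs$values[match(common, key_x), , ], length(common))
  Y <- matrix(ys$values[match(common, key_y), , ], length(common))
  ok <- !is.na(X) & !is.na(Y)
  X[!ok] <- NA; Y[!ok] <- NA
  n <- colSums(ok)
  sx <- colSums(X, na.rm = TRUE); sy <- colSums(Y, na.rm = TRUE)
  sxx <- colSums(X^2, na.rm = TRUE); syy <- colSums(Y^2, na.rm = TRUE)
  sxy <- colSums(X * Y, na.rm = TRUE)
  vx <- sxx - sx^2 / pmax(n, 1); vy <- syy - sy^2 / pmax(n, 1)
  cxy <- sxy - sx * sy / pmax(n, 1)
  np <- g$nrow * g$ncol
  slope <- rep(1, np); intercept <- rep(0, np)
  r <- rep(NA_real_, np); rmse <- rep(NA_real_, np)
  method <- rep(0L, np)
  fit_ok <- n >= min_pairs & vx > 1e-12
  if (any(n < min_pairs))
    warning(sprintf("%d pixels below %d overlap pairs: identity calibration",
                    sum(n < min_pairs & n > 0) + sum(n == 0), min_pairs))
  slope[fit_ok] <- cxy[fit_ok] / vx[fit_ok]
  intercept[fit_ok] <- (sy[fit_ok] - slope[fit_ok] * sx[fit_ok]) / n[fit_ok]
  method[fit_ok] <- 1L
  r[fit_ok] <- cxy[fit_ok] / sqrt(vx[fit_ok] * pmax(vy[fit_ok], 1e-300))
  res2 <- syy - 2 * intercept * sy - 2 * slope * sxy +
    n * intercept^2 + 2 * slope * intercept * sx + slope^2 * sxx
  rmse[fit_ok] <- sqrt(pmax(0, res2[fit_ok]) / n[fit_ok])
  smooths <- list()
  ebf <- which(as.vector(biome$codes) == BIOME_CODES[["EBF"]] & fit_ok)
  for (p in ebf) {
    x <- X[, p]; y <- Y[, p]
    keep <- !is.na(x)
    kk <- min(k, length(unique(x[keep])) - 1L)
    if (kk < 3) next                                  # too degenerate: keep OLS
    gm <- tryCatch(
      mgcv::gam(y ~ s(x, k = kk, bs = "cr"),
                data = data.frame(x = x[keep], y = y[keep])),
      error = function(e) NULL)
    if (is.null(gm)) next
    method[p] <- 2L
    fitted <- stats::fitted(gm)
    r[p] <- stats::cor(fitted, y[keep])
    rmse[p] <- sqrt(mean((fitted - y[keep])^2))
    smooths[[as.character(p)]] <- gm
  }
  shape <- function(v) matrix(v, g$nrow, g$ncol)
  structure(list(slope = shape(slope), intercept = shape(intercept),
                 r = shape(r), rmse = shape(rmse), n = shape(n),
                 method = shape(method), smooths = smooths, grid = g,
                 overlap_years = overlap_years, min_pairs = min_pairs),
            class = "pixel_calibration")
}

#' Apply pixel-wise calibrations to the solely record
#'
#' Linear pixels are mapped through `slope * x + intercept`, smooth pixels
#' through their fitted spline, identity-flagged pixels pass through.
#' Outputs are clipped to [0, 1]; fill propagates and the QC layer is
#' carried over.
#'
#' @param calibrations a `pixel_calibration`.
#' @param solely an FPAR `raster_cube` on the same grid.
#' @param years optional: restrict application to these years.
#' @return a calibrated FPAR `raster_cube`.
#' @export
apply_pixel_calibration <- function(calibrations, solely, years = NULL) {
  if (!same_grid(calibrations$grid, solely$grid)) stop("grids do not match")
  cube <- if (is.null(years)) solely else cube_subset_time(solely, years = years)
  nt <- nrow(cube$time)
  np <- prod(dim(cube$values)[2:3])
  V <- matrix(cube$values, nt, np)
  a <- as.vector(calibrations$intercept)
  b <- as.vector(calibrations$slope)
  meth <- as.vector(calibrations$method)
  lin <- meth == 1L
  V[, lin] <- sweep(sweep(V[, lin, drop = FALSE], 2, b[lin], "*"),
                    2, a[lin], "+")
  for (pc in names(calibrations$smooths)) {
    p <- as.integer(pc)
    x <- V[, p]
    keep <- !is.na(x)
    if (any(keep))
      V[keep, p] <- as.vector(
        stats::predict(calibrations$smooths[[pc]],
                       newdata = data.frame(x = x[keep])))
  }
  raster_cube(array(clip01(V), dim(cube$values)), cube$time, cube$grid,
              qc = cube$qc, varname = "fpar")
}

#' Assemble the final spliced product
#'
#' Concatenates the calibrated early record and the benchmark-sourced late
#' record into one cube; the two must abut exactly at the splice (last
#' early scene = (splice year - 1, period 24), first late scene =
#' (splice year, period 1)). Per-scene provenance tags record the source.
#'
#' @param calibrated_early FPAR `raster_cube` before the splice year.
#' @param benchmark_late FPAR `raster_cube` from the splice year onward.
#' @param splice_year first year sourced from the benchmark.
#' @return an FPAR `raster_cube` with a per-scene `provenance` field
#'   (`"calibrated"` / `"benchmark"`).
#' @export
assemble_product <- function(calibrated_early, benchmark_late, splice_year) {
  if (!same_grid(calibrated_early$grid, benchmark_late$grid))
    stop("grids do not match")
  et <- calibrated_early$time; lt <- benchmark_late$time
  if (any(et$year >= splice_year) || any(lt$year < splice_year))
    stop("scenes overlap the splice year on the wrong side")
  last_early <- et[nrow(et), ]
  first_late <- lt[1, ]
  if (!(last_early$year == splice_year - 1 && last_early$period == 24 &&
        first_late$year == splice_year && first_late$period == 1))
    stop("records do not abut at the splice year (gap or truncation)")
  vals <- array(NA_real_, c(nrow(et) + nrow(lt),
                            calibrated_early$grid$nrow,
                            calibrated_early$grid$ncol))
  vals[seq_len(nrow(et)), , ] <- calibrated_early$values
  vals[nrow(et) + seq_len(nrow(lt)), , ] <- benchmark_late$values
  qc <- array(2L, dim(vals))
  qc[seq_len(nrow(et)), , ] <- calibrated_early$qc
  qc[nrow(et) + seq_len(nrow(lt)), , ] <- benchmark_late$qc
  raster_cube(vals, rbind(et, lt), calibrated_early$grid, qc = qc,
              varname = "fpar",
              provenance = c(rep("calibrated", nrow(et)),
                             rep("benchmark", nrow(lt))))
}
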