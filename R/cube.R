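#' Raster time-series cube
#'
#' A `raster_cube` holds one variable on a regular geographic grid over a
#' half-monthly time axis: a numeric array with dimensions (time, row, col),
#' an integer QC array of the same shape (codes 0 and 1 mean usable; larger
#' codes mean contaminated), and the time axis as (year, period) pairs.
#' Fill values are stored as `NA`.
#'
#' @param values numeric array, dim = (n_time, nrow, ncol).
#' @param time data.frame with columns `year` and `period` (1..24), one row
#'   per time slice.
#' @param grid a [grid_spec()].
#' @param qc optional integer array matching `values`; defaults to 0 where
#'   valid and 2 where fill.
#' @param varname `"fpar"` or `"ndvi"`; sets the admissible value range.
#' @param provenance optional character vector, one tag per scene.
#' @return an object of class `raster_cube`.
#' @export
raster_cube <- function(values, time, grid, qc = NULL,
                        varname = c("fpar", "ndvi"), provenance = NULL) {
  varname <- match.arg(varname)
  stopifnot(length(dim(values)) == 3L)
  if (dim(values)[1] != nrow(time))
    stop("time axis length does not match first array dimension")
  if (dim(values)[2] != grid$nrow || dim(values)[3] != grid$ncol)
    stop("array shape does not match grid")
  rng <- if (varname == "fpar") c(0, 1) else c(-1, 1)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < rng[1] - 1e-9 || max(v) > rng[2] + 1e-9))
    stop(sprintf("%s values outside [%g, %g]", varname, rng[1], rng[2]))
  if (is.null(qc)) {
    qc <- array(0L, dim(values))
    qc[is.na(values)] <- 2L
  }
  stopifnot(all(dim(qc) == dim(values)))
  if (!is.null(provenance)) stopifnot(length(provenance) == nrow(time))
  structure(list(values = values, qc = qc,
                 time = data.frame(year = as.integer(time$year),
                                   period = as.integer(time$period)),
                 grid = grid, varname = varname, provenance = provenance),
            class = "raster_cube")
}

#' @export
print.raster_cube <- function(x, ...) {
  cat(sprintf("<raster_cube> %s: %d scenes (%d-%d), %d x %d cells at %.4f deg\n",
              x$varname, nrow(x$time), min(x$time$year), max(x$time$year),
              x$grid$nrow, x$grid$ncol, x$grid$res))
  cat(sprintf("  fill: %.1f%%  qc-good: %.1f%%\n",
              100 * mean(is.na(x$values)), 100 * mean(x$qc <= 1L)))
  invisible(x)
}

#' Subset a cube along the time axis
#'
#' @param cube a `raster_cube`.
#' @param years keep scenes from these years (NULL keeps all).
#' @param periods keep these half-month periods (NULL keeps all).
#' @return a `raster_cube`.
#' @export
cube_subset_time <- function(cube, years = NULL, periods = NULL) {
  keep <- rep(TRUE, nrow(cube$time))
  if (!is.null(years)) keep <- keep & cube$time$year %in% years
  if (!is.null(periods)) keep <- keep & cube$time$period %in% periods
  raster_cube(cube$values[keep, , , drop = FALSE], cube$time[keep, ],
              cube$grid, qc = cube$qc[keep, , , drop = FALSE],
              varname = cube$varname,
              provenance = if (!is.null(cube$provenance)) cube$provenance[keep])
}

#' Extract one pixel's time series from a cube
#'
#' @param cube a `raster_cube`.
#' @param row,col cell indices.
#' @return numeric vector along the cube's time axis (NA = fill).
#' @export
cube_pixel_series <- function(cube, row, col) cube$values[, row, col]

#' Scene index of a (year, period) pair
#' @param cube a `raster_cube`.
#' @param year,period scene stamp.
#' @return integer index into the time axis, NA if absent.
#' @export
cube_scene_index <- function(cube, year, period) {
  match(paste(year, period), paste(cube$time$year, cube$time$period))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Biome map
#'
#' Categorical grid over the eight vegetated biome classes plus
#' non-vegetated (code 0). Classes follow the LAI legacy scheme:
#' grasslands (GRA), shrublands (SHR), broadleaf croplands (CRO), savannas
#' (SAV), evergreen broadleaf forests (EBF), deciduous broadleaf forests
#' (DBF), evergreen needleleaf forests (ENF), deciduous needleleaf forests
#' (DNF).
#'
#' @param codes integer matrix of class codes (0 = non-vegetated, 1..8 the
#'   vegetated classes in the order above).
#' @param grid a [grid_spec()] with matching shape.
#' @param year optional year label.
#' @return an object of class `biome_map`.
#' @export
biome_map <- function(codes, grid, year = NA_integer_) {
  stopifnot(is.matrix(codes), nrow(codes) == grid$nrow, ncol(codes) == grid$ncol)
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  if (any(is.na(codes)) || any(codes < 0L | codes > 8L))
    stop("biome codes must be integers in 0..8 with no missing cells")
  structure(list(codes = codes, grid = grid, year = as.integer(year)),
            class = "biome_map")
}

#' @rdname biome_map
#' @format NULL
#' @export
BIOME_CODES <- c(GRA = 1L, SHR = 2L, CRO = 3L, SAV = 4L,
                 EBF = 5L, DBF = 6L, ENF = 7L, DNF = 8L)

#' @rdname biome_map
#' @param code integer biome code(s).
#' @export
biome_name <- function(code) {
  nm <- c("nonveg", names(BIOME_CODES))[code + 1L]
  nm
}

#' @export
print.biome_map <- function(x, ...) {
  tab <- table(factor(x$codes, levels = 0:8, labels = c("nonveg", names(BIOME_CODES))))
  cat(sprintf("<biome_map> %d x %d cells (year %s)\n", x$grid$nrow, x$grid$ncol,
              ifelse(is.na(x$year), "?", x$year)))
  print(tab)
  invisible(x)
}

# Evaluate an expression under a private, restored RNG stream. All generator
# seeds are derived from the world seed via small integer offsets.
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
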