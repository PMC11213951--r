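#' Regular geographic grid specification
#'
#' Describes a regular lat/lon grid by its north-west corner, cell size and
#' shape. Rows run north to south, columns west to east; coordinates are
#' degrees and cell centers sit half a cell inside the edges, the registration
#' convention used by half-monthly FPAR climate data records.
#'
#' @param nrow,ncol grid shape (cells).
#' @param res cell size in degrees (default 1/12 degree).
#' @param lat_max latitude of the northern grid edge.
#' @param lon_min longitude of the western grid edge.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, res = 1 / 12, lat_max = 40, lon_min = -10) {
  stopifnot(nrow >= 1, ncol >= 1, res > 0)
  lat_min <- lat_max - nrow * res
  lon_max <- lon_min + ncol * res
  if (lat_max > 90 || lat_min < -90)
    stop("latitude bounds must lie within [-90, 90]")
  if (lon_min < -180 || lon_max > 180)
    stop("longitude bounds must lie within [-180, 180]")
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol), res = res,
         lat_max = lat_max, lon_min = lon_min,
         lat_min = lat_min, lon_max = lon_max),
    class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @export
lat_centers <- function(grid) grid$lat_max - (seq_len(grid$nrow) - 0.5) * grid$res

#' @rdname grid_spec
#' @export
lon_centers <- function(grid) grid$lon_min + (seq_len(grid$ncol) - 0.5) * grid$res

#' Map geographic coordinates to grid cells
#'
#' @param grid a `grid_spec`.
#' @param lat,lon coordinates in degrees.
#' @return a data.frame with integer `row`, `col`; NA outside the grid.
#' @export
cell_of <- function(grid, lat, lon) {
  row <- ceiling((grid$lat_max - lat) / grid$res)
  col <- ceiling((lon - grid$lon_min) / grid$res)
  row[lat == grid$lat_min] <- grid$nrow
  col[lon == grid$lon_max] <- grid$ncol
  bad <- row < 1 | row > grid$nrow | col < 1 | col > grid$ncol
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$res - b$res) < tol &&
    abs(a$lat_max - b$lat_max) < tol && abs(a$lon_min - b$lon_min) < tol
}

#' Half-month period of a calendar date
#'
#' The year is split into 24 fixed periods: period `2m - 1` covers days 1-15
#' of month `m`, period `2m` the remainder of the month.
#'
#' @param date a `Date` vector (or something coercible).
#' @return integer vector of periods in 1..24.
#' @export
half_month_of <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  as.integer(2L * m - (d <= 15L))
}

#' Half-monthly time axis
#'
#' @param years integer vector of (consecutive) years.
#' @return a data.frame with one row per scene: `year`, `period` (1..24).
#' @export
make_time_axis <- function(years) {
  data.frame(year = rep(as.integer(years), each = 24L),
             period = rep(1:24, times = length(years)))
}
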