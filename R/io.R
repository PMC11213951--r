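# Scene files are two-page TIFFs: page 1 the value band, page 2 the QC band.
# Values are quantized to scaled integers exactly as published FPAR records
# are (scale 1e-4, offset -1, so the NDVI range [-1, 1] maps to 0..20000);
# the reserved code 65535 encodes fill (the product convention's -9999) and
# is never confused with a data value. A JSON sidecar carries the grid
# registration, time stamp, provenance and reproducibility metadata.
SCENE_SCALE <- 1e-4
SCENE_OFFSET <- -1
SCENE_FILL <- 65535L
QC_FILL <- 255L

#' Write and read a product scene
#'
#' `write_scene` stores a value grid plus its QC grid as a two-page TIFF
#' with a JSON sidecar (`<path>.json`) holding the geotransform and
#' metadata; `read_scene` restores both exactly (values are quantized to
#' the documented 1e-4 scale on write).
#'
#' @param values numeric matrix (NA = fill) with values in [-1, 1].
#' @param qc integer matrix of QC codes (0..254; NA allowed).
#' @param path output path (`.tif`).
#' @param grid a [grid_spec()].
#' @param meta named list of extra sidecar fields (year, period,
#'   provenance, config hash, seed, ...).
#' @return `write_scene`: `path`, invisibly. `read_scene`: list with
#'   `values`, `qc`, `grid`, `meta`.
#' @export
write_scene <- function(values, qc, path, grid, meta = list()) {
  stopifnot(is.matrix(values), all(dim(qc) == dim(values)))
  v <- values
  bad <- !is.na(v) & (v < SCENE_OFFSET | v > 1)
  if (any(bad)) stop("values outside the encodable range [-1, 1]")
  k <- round((v - SCENE_OFFSET) / SCENE_SCALE)
  k[is.na(k)] <- SCENE_FILL
  q <- qc
  q[is.na(q)] <- QC_FILL
  tiff::writeTIFF(list(k / 65535, q / 65535), path, bits.per.sample = 16L,
                  compression = "LZW")
  sidecar <- c(list(nrow = grid$nrow, ncol = grid$ncol, res = grid$res,
                    lat_max = grid$lat_max, lon_min = grid$lon_min,
                    scale = SCENE_SCALE, offset = SCENE_OFFSET,
                    fill_code = SCENE_FILL), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read scene '%s': %s", path,
                                   conditionMessage(e))))
  if (length(pages) != 2)
    stop(sprintf("corrupt scene '%s': expected 2 pages, found %d",
                 path, length(pages)))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  k <- pages[[1]]
  v <- k * side$scale + side$offset
  v[k == side$fill_code] <- NA_real_
  q <- pages[[2]]
  storage.mode(q) <- "integer"
  q[q == QC_FILL] <- NA_integer_
  grid <- grid_spec(side$nrow, side$ncol, side$res, side$lat_max, side$lon_min)
  meta <- side[setdiff(names(side), c("nrow", "ncol", "res", "lat_max",
                                      "lon_min", "scale", "offset",
                                      "fill_code"))]
  list(values = v, qc = q, grid = grid, meta = meta)
}

#' Write and read a cube as a scene directory
#'
#' One TIFF per scene named `<product>_<year>_<period>.tif`, plus a scene
#' index CSV (`index.csv`: year, period, product, file, provenance) and a
#' cube-level `meta.json` recording the configuration hash and seed used to
#' produce the record.
#'
#' @param cube a `raster_cube`.
#' @param dir output directory (created).
#' @param product product tag used in file names and the index.
#' @param config_hash,seed reproducibility metadata stored in every sidecar.
#' @return `write_cube`: the index data.frame, invisibly; `read_cube`: a
#'   `raster_cube`.
#' @export
write_cube <- function(cube, dir, product, config_hash = NA_character_,
                       seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- nrow(cube$time)
  prov <- if (is.null(cube$provenance)) rep(NA_character_, nt) else cube$provenance
  files <- sprintf("%s_%04d_%02d.tif", product, cube$time$year,
                   cube$time$period)
  for (t in seq_len(nt)) {
    write_scene(matrix(cube$values[t, , ], cube$grid$nrow),
                matrix(cube$qc[t, , ], cube$grid$nrow),
                file.path(dir, files[t]), cube$grid,
                meta = list(year = cube$time$year[t],
                            period = cube$time$period[t],
                            product = product, provenance = prov[t],
                            varname = cube$varname,
                            config_hash = config_hash, seed = seed))
  }
  index <- data.frame(year = cube$time$year, period = cube$time$period,
                      product = product, file = files, provenance = prov)
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(list(product = product, varname = cube$varname,
                            config_hash = config_hash, seed = seed,
                            n_scenes = nt),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(index)
}

#' @rdname write_cube
#' @export
read_cube <- function(dir) {
  index <- utils::read.csv(file.path(dir, "index.csv"),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(index[c("year", "period", "product")]))
    stop("scene index contains duplicate (year, period, product) entries")
  first <- read_scene(file.path(dir, index$file[1]))
  g <- first$grid
  vals <- array(NA_real_, c(nrow(index), g$nrow, g$ncol))
  qc <- array(NA_integer_, dim(vals))
  varname <- if (!is.null(first$meta$varname)) first$meta$varname else "fpar"
  for (t in seq_len(nrow(index))) {
    sc <- if (t == 1) first else read_scene(file.path(dir, index$file[t]))
    vals[t, , ] <- sc$values
    qc[t, , ] <- sc$qc
  }
  qc[is.na(qc)] <- 2L
  prov <- if (all(is.na(index$provenance))) NULL else index$provenance
  raster_cube(vals, index[c("year", "period")], g, qc = qc,
              varname = varname, provenance = prov)
}
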