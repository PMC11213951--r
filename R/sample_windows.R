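#' Partition a grid into N x N spatial windows
#'
#' Non-overlapping tiles covering the grid; trailing partial tiles at the
#' south/east edges are kept as smaller windows, so every cell belongs to
#' exactly one window.
#'
#' @param grid_shape integer `c(nrow, ncol)`.
#' @param N window edge length in cells (clamped to the grid dimensions).
#' @return a data.frame with one row per window: `r0, r1, c0, c1` (inclusive
#'   cell ranges).
#' @export
partition_windows <- function(grid_shape, N) {
  stopifnot(N >= 1)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  r0 <- seq(1L, nr, by = N); c0 <- seq(1L, nc, by = N)
  out <- expand.grid(r0 = r0, c0 = c0)
  out$r1 <- pmin(out$r0 + N - 1L, nr)
  out$c1 <- pmin(out$c0 + N - 1L, nc)
  out[, c("r0", "r1", "c0", "c1")]
}

#' Dominant biomes of a window
#'
#' Biomes covering strictly more than 10% of the window's valid pixels.
#'
#' @param biome_codes integer vector (or matrix) of biome codes of the
#'   window's cells.
#' @param valid logical vector of the same length marking usable cells.
#' @param threshold dominance threshold on the valid-pixel share
#'   (strict `>`, default 0.10).
#' @return sorted integer vector of dominant vegetated biome codes (empty
#'   when no valid pixels).
#' @export
dominant_biomes <- function(biome_codes, valid, threshold = 0.10) {
  b <- as.vector(biome_codes)[as.vector(valid)]
  b <- b[b >= 1L & b <= 8L]
  if (!length(b)) return(integer(0))
  share <- tabulate(b, nbins = 8L) / sum(as.vector(valid))
  sort(which(share > threshold))
}

#' Extract window training samples
#'
#' For every window and every dominant biome within it, extracts the median
#' NDVI and median FPAR over that biome's usable pixels of a scene.
#' Usable pixels are those unfilled in both layers with an NDVI QC code of
#' 0 or 1; the medians of both variables are taken over the same pixel set.
#' Window-center coordinates are the geometric centers of the actual
#' (possibly clipped) extents.
#'
#' @param ndvi,fpar co-registered `raster_cube`s sharing a time axis subset.
#' @param biome a [biome_map()] on the same grid.
#' @param N window size in cells.
#' @param years,periods optional time filters (defaults: scenes common to
#'   both cubes).
#' @param biome_filter optional integer codes: keep only these biomes.
#' @return a data.frame of window samples: `ndvi`, `fpar`, `lat`, `lon`,
#'   `biome`, `period`, `year`, `window`.
#' @export
extract_window_samples <- function(ndvi, fpar, biome, N, years = NULL,
                                   periods = NULL, biome_filter = NULL) {
  if (!same_grid(ndvi$grid, fpar$grid) || !same_grid(ndvi$grid, biome$grid))
    stop("cubes and biome map must share one grid")
  key_n <- paste(ndvi$time$year, ndvi$time$period)
  key_f <- paste(fpar$time$year, fpar$time$period)
  common <- intersect(key_n, key_f)
  if (!is.null(years))
    common <- common[as.integer(sub(" .*", "", common)) %in% years]
  if (!is.null(periods))
    common <- common[as.integer(sub(".* ", "", common)) %in% periods]
  wins <- partition_windows(c(ndvi$grid$nrow, ndvi$grid$ncol), N)
  latc <- lat_centers(ndvi$grid); lonc <- lon_centers(ndvi$grid)
  rows <- list()
  for (k in common) {
    ti_n <- match(k, key_n); ti_f <- match(k, key_f)
    nv <- ndvi$values[ti_n, , ]; fv <- fpar$values[ti_f, , ]
    qc <- ndvi$qc[ti_n, , ]
    valid <- !is.na(nv) & !is.na(fv) & qc <= 1L
    for (w in seq_len(nrow(wins))) {
      rr <- wins$r0[w]:wins$r1[w]; cc <- wins$c0[w]:wins$c1[w]
      vw <- valid[rr, cc]
      if (!any(vw)) next
      bw <- biome$codes[rr, cc]
      doms <- dominant_biomes(bw, vw)
      if (!is.null(biome_filter)) doms <- intersect(doms, biome_filter)
      for (b in doms) {
        sel <- vw & bw == b
        if (!any(sel)) next
        rows[[length(rows) + 1L]] <- data.frame(
          ndvi = stats::median(nv[rr, cc][sel]),
          fpar = stats::median(fv[rr, cc][sel]),
          lat = mean(range(latc[rr])), lon = mean(range(lonc[cc])),
          biome = b,
          period = as.integer(sub(".* ", "", k)),
          year = as.integer(sub(" .*", "", k)),
          window = w)
      }
    }
  }
  if (!length(rows))
    return(data.frame(ndvi = numeric(0), fpar = numeric(0), lat = numeric(0),
                      lon = numeric(0), biome = integer(0), period = integer(0),
                      year = integer(0), window = integer(0)))
  do.call(rbind, rows)
}

#' Build the combined training-sample set with biome-specific window sizes
#'
#' Evergreen broadleaf forest samples are extracted with the small window
#' size, all other biomes with the default; the two sets are concatenated.
#'
#' @inheritParams extract_window_samples
#' @param N_default window size for non-EBF biomes (default 25).
#' @param N_ebf window size for EBF (default 11).
#' @return a data.frame of window samples.
#' @export
build_training_samples <- function(ndvi, fpar, biome, N_default = 25L,
                                   N_ebf = 11L, years = NULL, periods = NULL) {
  ebf <- BIOME_CODES[["EBF"]]
  a <- extract_window_samples(ndvi, fpar, biome, N_default, years, periods,
                              biome_filter = setdiff(1:8, ebf))
  b <- extract_window_samples(ndvi, fpar, biome, N_ebf, years, periods,
                              biome_filter = ebf)
  rbind(a, b)
}

#' Randomly split samples into train / validation / test sets
#'
#' Disjoint, exhaustive partition by record, reproducible under the seed.
#' Sizes are `round(n * fractions)` for the first two sets, the remainder
#' goes to the third.
#'
#' @param samples a data.frame of samples.
#' @param fractions length-3 fractions summing to 1 (default 70/15/15).
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test` data.frames.
#' @export
split_samples <- function(samples, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  n <- nrow(samples)
  if (n < 3) stop("need at least 3 samples to split")
  with_rng(seed, {
    ord <- sample.int(n)
    n1 <- round(n * fractions[1]); n2 <- round(n * fractions[2])
    list(train = samples[ord[seq_len(n1)], , drop = FALSE],
         val = samples[ord[n1 + seq_len(n2)], , drop = FALSE],
         test = samples[ord[(n1 + n2 + 1):n], , drop = FALSE])
  })
}
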