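# Empirical mode decomposition: sifting with natural-spline envelopes and
# mirrored boundary extrema. Kept internal; users call eemd_decompose().

# Indices of strict-neighborhood local maxima/minima (plateaus collapse to
# their first point).
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  d[d == 0] <- .Machine$double.eps            # break plateaus
  s <- sign(d)
  turn <- diff(s)
  list(max = which(turn < 0) + 1L, min = which(turn > 0) + 1L)
}

# Envelope through extrema, with two mirrored extrema beyond each end to tame
# spline end swings.
envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) < 2) return(NULL)
  i1 <- idx[1]; i2 <- idx[2]
  iL <- c(2 - i2, 2 - i1)                     # mirror about t = 1
  j1 <- idx[length(idx)]; j2 <- idx[length(idx) - 1]
  iR <- c(2 * n - j1, 2 * n - j2)
  tt <- c(iL, idx, iR)
  vv <- c(x[c(i2, i1)], x[idx], x[c(j1, j2)])
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "natural")$y
}

# Extract one intrinsic mode function by sifting; NULL when the input has
# too few extrema to oscillate.
sift_imf <- function(x, max_sift = 50L, tol = 0.2) {
  h <- x
  for (s in seq_len(max_sift)) {
    ex <- find_extrema(h)
    if (length(ex$max) < 2 || length(ex$min) < 2) {
      if (s == 1) return(NULL)
      break
    }
    upper <- envelope(h, ex$max)
    lower <- envelope(h, ex$min)
    if (is.null(upper) || is.null(lower)) break
    m <- (upper + lower) / 2
    h_new <- h - m
    denom <- sum(h^2)
    if (denom == 0) break
    if (sum((h - h_new)^2) / denom < tol^2) {
      h <- h_new
      break
    }
    h <- h_new
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by iterative
#' sifting with cubic-spline envelopes, stopping when the residual has too
#' few extrema to oscillate or the prescribed IMF count is reached.
#'
#' @param x numeric series without missing values.
#' @param max_imfs maximum number of IMFs extracted.
#' @return list with `imfs` (matrix, one column per IMF, possibly 0
#'   columns) and `residual`.
#' @export
emd_decompose <- function(x, max_imfs = 8L) {
  stopifnot(!anyNA(x))
  n <- length(x)
  imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  resid <- x
  for (k in seq_len(max_imfs)) {
    imf <- sift_imf(resid)
    if (is.null(imf)) break
    imfs <- cbind(imfs, imf)
    resid <- resid - imf
    ex <- find_extrema(resid)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
  }
  list(imfs = imfs, residual = resid)
}

#' Ensemble empirical mode decomposition
#'
#' Noise-assisted EMD: each ensemble member adds white noise with standard
#' deviation `noise_level * sd(x)` to the input, is decomposed by
#' [emd_decompose()], and the per-mode IMFs are averaged across members
#' (members short of a mode contribute zeros). The residual is defined as
#' the input minus the summed averaged IMFs, so the decomposition
#' reconstructs the input exactly. Defaults follow common practice for
#' these diagnostics: noise level 0.2, ensemble size 100, at most 8 IMFs.
#'
#' @param x numeric series without missing values (length >= 16 advised).
#' @param noise_level noise sd as a fraction of `sd(x)`.
#' @param ensemble number of ensemble members.
#' @param max_imfs prescribed maximum IMF count.
#' @param seed RNG seed.
#' @return object of class `eemd`: list with `imfs` (n x k matrix, k <=
#'   `max_imfs`), `residual`, and the parameters.
#' @export
eemd_decompose <- function(x, noise_level = 0.2, ensemble = 100L,
                           max_imfs = 8L, seed = 1L) {
  stopifnot(!anyNA(x))
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    out <- list(imfs = matrix(numeric(0), n, 0), residual = x,
                noise_level = noise_level, ensemble = ensemble,
                max_imfs = max_imfs)
    return(structure(out, class = "eemd"))
  }
  acc <- matrix(0, n, max_imfs)
  kmax <- 0L
  with_rng(seed, {
    for (e in seq_len(ensemble)) {
      xe <- x + stats::rnorm(n, sd = noise_level * s)
      dec <- emd_decompose(xe, max_imfs)
      k <- ncol(dec$imfs)
      if (k > 0) acc[, seq_len(k)] <- acc[, seq_len(k)] + dec$imfs
      kmax <- max(kmax, k)
    }
  })
  imfs <- acc[, seq_len(kmax), drop = FALSE] / ensemble
  residual <- x - if (kmax > 0) rowSums(imfs) else 0
  structure(list(imfs = imfs, residual = residual,
                 noise_level = noise_level, ensemble = ensemble,
                 max_imfs = max_imfs),
            class = "eemd")
}

#' @export
print.eemd <- function(x, ...) {
  cat(sprintf("<eemd> %d IMFs + residual (n = %d, noise %.2f, ensemble %d)\n",
              ncol(x$imfs), length(x$residual), x$noise_level, x$ensemble))
  invisible(x)
}
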