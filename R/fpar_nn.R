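#' Regression accuracy metrics
#'
#' R-squared (1 - SS_res/SS_tot), RMSE, MAE, and MAPE. MAPE is computed only
#' over observations above a small guard `eps` (near-zero FPAR observations
#' would blow the relative error up) and reported as `NA` when no
#' observation exceeds the guard. A constant observation vector has no
#' defined R-squared; it is reported as 0 with a warning.
#'
#' @param pred,obs equal-length numeric vectors (pairs with NA dropped).
#' @param eps MAPE guard on the observation magnitude (default 0.01).
#' @return an object of class `metric_set`: list with `r2`, `rmse`, `mae`,
#'   `mape` (percent).
#' @export
regression_metrics <- function(pred, obs, eps = 0.01) {
  stopifnot(length(pred) == length(obs))
  keep <- !is.na(pred) & !is.na(obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(obs) < 2) stop("need at least 2 pairs")
  err <- pred - obs
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant observations: R-squared undefined, reported as 0")
    0
  } else 1 - sum(err^2) / ss_tot
  big <- abs(obs) > eps
  mape <- if (any(big)) 100 * mean(abs(err[big]) / abs(obs[big])) else NA_real_
  structure(list(r2 = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 mape = mape, n = length(obs)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 = %.4f  RMSE = %.4f  MAE = %.4f  MAPE = %s%%  (n = %d)\n",
              x$r2, x$rmse, x$mae,
              ifelse(is.na(x$mape), "NA", sprintf("%.2f", x$mape)), x$n))
  invisible(x)
}

# Feature matrix for the per-period network: standardized NDVI and window
# center coordinates plus a one-hot biome encoding.
nn_features <- function(df, biome_levels, center = NULL, scale = NULL) {
  X <- cbind(ndvi = df$ndvi, lat = df$lat, lon = df$lon)
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  onehot <- outer(df$biome, biome_levels, `==`) * 1
  colnames(onehot) <- paste0("b", biome_levels)
  list(X = cbind(Xs, onehot), center = center, scale = scale)
}

#' Train a feed-forward FPAR regression network
#'
#' One hidden layer (via `nnet`), linear output, standardized continuous
#' inputs (NDVI, window-center latitude and longitude) and one-hot biome
#' encoding; the benchmark FPAR median is the target. Training is
#' deterministic under the seed. The network's capacity and shrinkage are
#' governed by the hidden-node count and the weight-decay penalty, the two
#' hyperparameters exposed to the search in [tune_hyperparameters()].
#'
#' @param train,val data.frames of window samples (see
#'   [extract_window_samples()]); validation RMSE is stored for model
#'   selection.
#' @param size hidden-node count.
#' @param decay weight-decay penalty.
#' @param maxit optimizer iteration cap.
#' @param seed RNG seed for the weight initialization.
#' @return an object of class `bpnn`.
#' @export
train_bpnn <- function(train, val, size = 8L, decay = 1e-3, maxit = 500L,
                       seed = 1L) {
  stopifnot(nrow(train) > 0, nrow(val) > 0)
  if (stats::var(train$fpar) == 0)
    warning("degenerate (constant) training target")
  biome_levels <- sort(unique(train$biome))
  ft <- nn_features(train, biome_levels)
  fit <- with_rng(seed,
    nnet::nnet(ft$X, train$fpar, size = size, decay = decay, linout = TRUE,
               maxit = maxit, trace = FALSE, MaxNWts = 10000L))
  model <- structure(list(fit = fit, center = ft$center, scale = ft$scale,
                          biome_levels = biome_levels, size = size,
                          decay = decay, seed = seed),
                     class = "bpnn")
  model$val_rmse <- sqrt(mean((predict_bpnn(model, val) - val$fpar)^2))
  model
}

#' @rdname train_bpnn
#' @param model a `bpnn`.
#' @param newdata data.frame with `ndvi`, `lat`, `lon`, `biome`.
#' @return numeric predictions (unclipped).
#' @export
predict_bpnn <- function(model, newdata) {
  f <- nn_features(newdata, model$biome_levels, model$center, model$scale)
  as.vector(stats::predict(model$fit, f$X))
}

# Evaluate one (N, size, decay) configuration: mean validation RMSE over
# seeded repetitions; returns the repetition models too.
eval_nn_config <- function(splits, size, decay, repetitions, seed, maxit = 500L) {
  fits <- lapply(seq_len(repetitions), function(r)
    train_bpnn(splits$train, splits$val, size = size, decay = decay,
               maxit = maxit, seed = seed + r))
  list(mean_val_rmse = mean(vapply(fits, `[[`, numeric(1), "val_rmse")),
       fits = fits)
}

#' Sequential model-based hyperparameter and window-size search
#'
#' Minimizes the repetition-averaged validation RMSE over hidden-node count,
#' weight decay and spatial window size, using a Gaussian-process surrogate
#' (via `kernlab::gausspr`) with expected-improvement acquisition after a
#' seeded random initial design. The winning configuration is returned with
#' its repetition-averaged test metrics and its best repetition model.
#'
#' @param samples_by_N named list of window-sample data.frames keyed by the
#'   window size N used to build them (e.g. `list("11" = ..., "25" = ...)`).
#' @param size_range integer range of hidden-node counts.
#' @param decay_range range of the weight-decay penalty (searched on a
#'   log10 scale).
#' @param budget total number of configurations evaluated (>= 1).
#' @param repetitions seeded repetitions per configuration whose validation
#'   RMSE is averaged (default 10).
#' @param seed RNG seed.
#' @param fractions train/val/test split fractions.
#' @param maxit optimizer iteration cap per fit.
#' @return list with `best` (N, size, decay), `model` (a `bpnn`), `metrics`
#'   (repetition-averaged test `metric_set`), and the evaluation `history`.
#' @export
tune_hyperparameters <- function(samples_by_N, size_range = c(4L, 24L),
                                 decay_range = c(1e-4, 1e-1), budget = 25L,
                                 repetitions = 10L, seed = 1L,
                                 fractions = c(0.7, 0.15, 0.15),
                                 maxit = 500L) {
  stopifnot(budget >= 1, length(samples_by_N) >= 1)
  Ns <- as.integer(names(samples_by_N))
  if (any(is.na(Ns))) stop("samples_by_N must be keyed by window size")
  splits <- lapply(samples_by_N, split_samples, fractions = fractions,
                   seed = seed)
  draw_config <- function(u) {
    # u: numeric triple in [0,1]^3 -> (N index, size, log-decay)
    list(N = Ns[1L + floor(u[1] * length(Ns) * 0.999999)],
         size = as.integer(round(size_range[1] + u[2] * diff(size_range))),
         decay = 10^(log10(decay_range[1]) +
                       u[3] * diff(log10(decay_range))))
  }
  history <- data.frame()
  evals <- list()
  score <- function(cfg) {
    ev <- eval_nn_config(splits[[as.character(cfg$N)]], cfg$size, cfg$decay,
                         repetitions, seed, maxit)
    evals[[length(evals) + 1L]] <<- ev
    history <<- rbind(history, data.frame(N = cfg$N, size = cfg$size,
                                          decay = cfg$decay,
                                          val_rmse = ev$mean_val_rmse))
    ev$mean_val_rmse
  }
  n_init <- min(budget, max(3L, budget %/% 3L))
  with_rng(seed * 7L + 11L, {
    for (i in seq_len(n_init)) score(draw_config(stats::runif(3)))
    while (nrow(history) < budget) {
      Z <- cbind(match(history$N, Ns) / length(Ns),
                 (history$size - size_range[1]) / max(1, diff(size_range)),
                 (log10(history$decay) - log10(decay_range[1])) /
                   diff(log10(decay_range)))
      cand_u <- matrix(stats::runif(3 * 128L), ncol = 3)
      acq <- tryCatch({
        gp <- kernlab::gausspr(Z, history$val_rmse, variance.model = TRUE,
                               scaled = FALSE)
        mu <- kernlab::predict(gp, cand_u)
        sdev <- kernlab::predict(gp, cand_u, type = "sdeviation")
        best <- min(history$val_rmse)
        z <- (best - mu) / pmax(sdev, 1e-9)
        (best - mu) * stats::pnorm(z) + sdev * stats::dnorm(z)   # EI
      }, error = function(e) stats::runif(nrow(cand_u)))
      acq <- as.vector(acq)
      acq[!is.finite(acq)] <- -Inf
      pick <- if (all(acq == -Inf)) sample.int(nrow(cand_u), 1L)
              else which.max(acq)
      score(draw_config(cand_u[pick, ]))
    }
  })
  win <- which.min(history$val_rmse)
  ev <- evals[[win]]
  best_fit <- ev$fits[[which.min(vapply(ev$fits, `[[`, numeric(1), "val_rmse"))]]
  sp <- splits[[as.character(history$N[win])]]
  test_metrics <- lapply(ev$fits, function(f)
    regression_metrics(predict_bpnn(f, sp$test), sp$test$fpar))
  avg <- lapply(c("r2", "rmse", "mae", "mape"), function(k)
    mean(vapply(test_metrics, `[[`, numeric(1), k), na.rm = TRUE))
  names(avg) <- c("r2", "rmse", "mae", "mape")
  metrics <- structure(c(avg, list(n = nrow(sp$test))), class = "metric_set")
  list(best = as.list(history[win, c("N", "size", "decay")]),
       model = best_fit, metrics = metrics, history = history)
}

#' Train one half-month period model with fixed hyperparameters
#'
#' Splits the period's samples 70/15/15, trains `repetitions` seeded
#' networks, keeps the one with the lowest validation RMSE for deployment,
#' and reports test metrics averaged over the repetitions.
#'
#' @param samples window-sample data.frame (all periods; filtered here).
#' @param period half-month period 1..24.
#' @param size,decay,maxit network settings, see [train_bpnn()].
#' @param repetitions number of seeded fits.
#' @param seed RNG seed.
#' @return an object of class `period_model`.
#' @export
train_period_model <- function(samples, period, size = 8L, decay = 1e-3,
                               repetitions = 3L, seed = 1L, maxit = 500L) {
  df <- samples[samples$period == period, , drop = FALSE]
  if (nrow(df) < 10) stop(sprintf("too few samples for period %d", period))
  sp <- split_samples(df, seed = seed)
  ev <- eval_nn_config(sp, size, decay, repetitions, seed, maxit)
  fit <- ev$fits[[which.min(vapply(ev$fits, `[[`, numeric(1), "val_rmse"))]]
  tm <- lapply(ev$fits, function(f)
    regression_metrics(predict_bpnn(f, sp$test), sp$test$fpar))
  avg <- lapply(c("r2", "rmse", "mae", "mape"), function(k)
    mean(vapply(tm, `[[`, numeric(1), k), na.rm = TRUE))
  names(avg) <- c("r2", "rmse", "mae", "mape")
  structure(list(period = as.integer(period), fit = fit, size = size,
                 decay = decay,
                 metrics = structure(c(avg, list(n = nrow(sp$test))),
                                     class = "metric_set"),
                 val_rmse = fit$val_rmse),
            class = "period_model")
}

#' Predict an FPAR grid from NDVI scenes with a period model
#'
#' Applies the trained network pixel-wise to every scene of the NDVI cube
#' whose half-month period matches the model, using the pixel's NDVI,
#' cell-center coordinates and biome class. Predictions are clipped to
#' [0, 1]; fill or QC-bad NDVI pixels, non-vegetated cells and biome
#' classes outside the training set yield fill (the latter with a warning).
#' The QC layer is inherited from the NDVI input.
#'
#' @param model a `period_model` (or `bpnn` with a `period` attached via
#'   `model$period`).
#' @param ndvi an NDVI `raster_cube`.
#' @param biome a [biome_map()] on the same grid.
#' @return an FPAR `raster_cube` of the matching scenes.
#' @export
predict_fpar_grid <- function(model, ndvi, biome) {
  if (!same_grid(ndvi$grid, biome$grid)) stop("grids do not match")
  keep <- ndvi$time$period == model$period
  if (!any(keep)) stop("no scene matches the model period")
  sub <- cube_subset_time(ndvi, periods = model$period)
  fit <- if (inherits(model, "period_model")) model$fit else model
  grid <- sub$grid
  latm <- matrix(rep(lat_centers(grid), grid$ncol), grid$nrow)
  lonm <- matrix(rep(lon_centers(grid), each = grid$nrow), grid$nrow)
  codes <- as.vector(biome$codes)
  known <- codes %in% fit$biome_levels
  if (any(codes >= 1 & codes <= 8 & !known))
    warning("biome class outside training classes: filled")
  vals <- array(NA_real_, dim(sub$values))
  for (t in seq_len(nrow(sub$time))) {
    nv <- as.vector(sub$values[t, , ])
    ok <- !is.na(nv) & as.vector(sub$qc[t, , ]) <= 1L & known
    if (!any(ok)) next
    df <- data.frame(ndvi = nv[ok], lat = as.vector(latm)[ok],
                     lon = as.vector(lonm)[ok], biome = codes[ok])
    v <- rep(NA_real_, length(nv))
    v[ok] <- clip01(predict_bpnn(fit, df))
    vals[t, , ] <- matrix(v, grid$nrow, grid$ncol)
  }
  raster_cube(vals, sub$time, grid, qc = sub$qc, varname = "fpar")
}

#' Predict the full solely FPAR record from all period models
#'
#' @param models list of 24 `period_model`s (indexed by period).
#' @param ndvi NDVI `raster_cube`.
#' @param biome a [biome_map()].
#' @return an FPAR `raster_cube` on the NDVI time axis.
#' @export
predict_solely <- function(models, ndvi, biome) {
  vals <- array(NA_real_, dim(ndvi$values))
  for (m in models) {
    part <- suppressWarnings(predict_fpar_grid(m, ndvi, biome))
    idx <- which(ndvi$time$period == m$period)
    vals[idx, , ] <- part$values
  }
  raster_cube(vals, ndvi$time, ndvi$grid, qc = ndvi$qc, varname = "fpar")
}
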