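#' Named analysis-period presets
#'
#' The conventional evaluation windows of long-term FPAR inter-comparison:
#' p1 = 1982-2016, p2 = 1982-2003, p3 = 2004-2016.
#'
#' @return named list of year vectors.
#' @export
period_presets <- function() {
  list(p1 = 1982:2016, p2 = 1982:2003, p3 = 2004:2016)
}

#' Run the full FPAR record construction and evaluation pipeline
#'
#' Orchestrates every stage over a synthetic world: input simulation,
#' benchmark smoothing, window sampling, per-period network training,
#' solely-record prediction, pixel-wise integration and splicing,
#' high-resolution reference-sample generation, and the consistency
#' evaluation suite. Stages build on one another; requesting a later stage
#' runs the earlier ones it needs. All randomness derives from `seed`.
#'
#' @param config a [world_config()].
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "preprocess", "sample", "train", "integrate",
#'   "reference", "evaluate")`; `"all"` runs everything.
#' @param seed master seed (defaults to the config seed; overrides it).
#' @param outdir optional directory: scene TIFFs, index CSVs and metric
#'   tables are written beneath it.
#' @param nn list of network settings: `size`, `decay`, `repetitions`,
#'   `maxit`.
#' @param reference list of reference-stage settings: `train_per_biome`
#'   (training locations per non-DNF biome; DNF gets 0.7 of it),
#'   `stamps_per_location`, `n_ref_cells`, `ref_year_stride`,
#'   `min_pairs`, `heterogeneity`, `qa_bad_frac`.
#' @param n_ground_sites ground network size for direct validation.
#' @param verbose print stage progress.
#' @return a list of artifacts (cubes, models, calibration, reference
#'   samples, evaluation tables) for the stages run.
#' @export
run_pipeline <- function(config, stages = "all", seed = config$seed,
                         outdir = NULL,
                         nn = list(size = 8L, decay = 1e-3,
                                   repetitions = 3L, maxit = 300L),
                         reference = list(train_per_biome = 120L,
                                          stamps_per_location = 6L,
                                          n_ref_cells = 30L,
                                          ref_year_stride = 2L,
                                          min_pairs = 60L,
                                          heterogeneity = 0.05,
                                          qa_bad_frac = 0.05),
                         n_ground_sites = 25L, verbose = TRUE) {
  all_stages <- c("simulate", "preprocess", "sample", "train", "integrate",
                  "reference", "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage: ", paste(setdiff(stages, all_stages), collapse = ", "))
  # run every prerequisite of the latest requested stage
  stages <- all_stages[seq_len(max(match(stages, all_stages)))]
  config$seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  art <- list(config = config, config_hash = hash, seed = config$seed)
  overlap <- config$benchmark_start:config$ndvi_end

  say("[simulate] generating synthetic world (seed %d)", config$seed)
  map_years <- max(config$years[1], max(config$years) - 19):max(config$years)
  art$yearly_maps <- lapply(map_years, generate_biome_map, config = config)
  art$major_biome <- majority_biome_map(art$yearly_maps)
  art$truth <- generate_truth_fpar(art$major_biome, config)
  art$ndvi_clean <- simulate_sensor_ndvi(art$truth, art$major_biome, config,
                                         artifacts = FALSE)
  art$ndvi_artifact <- simulate_sensor_ndvi(art$truth, art$major_biome, config,
                                            artifacts = TRUE)
  art$benchmark_raw <- simulate_si_fpar(art$truth, config,
                                        biome = art$major_biome)
  art$ground <- simulate_ground_sites(art$truth, config, n_ground_sites,
                                      biome = art$major_biome)
  if (!"preprocess" %in% stages) return(finish_pipeline(art, outdir))

  say("[preprocess] weighted Savitzky-Golay smoothing of the benchmark")
  art$benchmark <- savgol_cube(art$benchmark_raw)
  if (!"sample" %in% stages) return(finish_pipeline(art, outdir))

  say("[sample] extracting window samples over the %d-%d overlap",
      min(overlap), max(overlap))
  art$samples <- build_training_samples(art$ndvi_clean, art$benchmark,
                                        art$major_biome, years = overlap)
  if (!"train" %in% stages) return(finish_pipeline(art, outdir))

  say("[train] fitting %d per-period models", 24L)
  art$models <- lapply(1:24, function(p)
    train_period_model(art$samples, p, size = nn$size, decay = nn$decay,
                       repetitions = nn$repetitions, seed = config$seed + p,
                       maxit = nn$maxit))
  say("[train] predicting the solely record")
  art$solely <- predict_solely(art$models, art$ndvi_clean, art$major_biome)
  art$solely_artifact <- predict_solely(art$models, art$ndvi_artifact,
                                        art$major_biome)
  if (!"integrate" %in% stages) return(finish_pipeline(art, outdir))

  say("[integrate] pixel-wise calibration and splice at %d", config$splice_year)
  art$calibration <- suppressWarnings(
    fit_pixel_calibration(art$solely, art$benchmark, art$major_biome,
                          overlap_years = overlap))
  early <- apply_pixel_calibration(
    art$calibration, art$solely,
    years = config$years[1]:(config$splice_year - 1))
  late <- cube_subset_time(art$benchmark,
                           years = config$splice_year:max(config$years))
  art$product <- assemble_product(early, late, config$splice_year)
  if (!"reference" %in% stages) return(finish_pipeline(art, outdir))

  say("[reference] building reference pairs and forest regressors")
  art$reference <- build_reference_stage(art, config, reference)
  if (!"evaluate" %in% stages) return(finish_pipeline(art, outdir))

  say("[evaluate] running the consistency-evaluation suite")
  art$evaluation <- evaluate_stage(art, config)
  finish_pipeline(art, outdir)
}

# Reference-sample stage: training pairs, regressor bank, predictions.
build_reference_stage <- function(art, config, opt) {
  counts <- stats::setNames(rep(opt$train_per_biome, 8L), names(BIOME_CODES))
  counts[["DNF"]] <- round(0.7 * opt$train_per_biome)
  locs <- select_sample_locations(art$major_biome, counts,
                                  yearly_maps = art$yearly_maps,
                                  seed = config$seed + 101L)
  bench_years <- config$benchmark_start:max(config$years)
  train_locs <- locs[rep(seq_len(nrow(locs)), each = opt$stamps_per_location), ]
  stamp <- with_rng(config$seed + 102L, {
    yr <- sample(bench_years, nrow(train_locs), replace = TRUE)
    data.frame(year = yr, period = sample(1:24, nrow(train_locs),
                                          replace = TRUE))
  })
  train_locs$year <- stamp$year
  train_locs$period <- stamp$period
  patches <- simulate_landsat_patches(art$truth, train_locs, config,
                                      heterogeneity = opt$heterogeneity,
                                      qa_bad_frac = opt$qa_bad_frac,
                                      seed = config$seed + 103L)
  pairs <- build_reference_pairs(patches, art$benchmark, art$major_biome)
  models <- if (is.null(pairs)) list()
            else train_reference_regressors(pairs, min_pairs = opt$min_pairs,
                                            seed = config$seed + 104L)
  # prediction cells and scenes
  veg <- which(art$major_biome$codes > 0L)
  cells <- with_rng(config$seed + 105L,
                    sample(veg, min(opt$n_ref_cells, length(veg))))
  rc <- arrayInd(cells, c(config$grid$nrow, config$grid$ncol))
  pred_years <- seq(max(1984, config$years[1]), max(config$years),
                    by = opt$ref_year_stride)
  groups <- list()
  for (i in seq_len(nrow(rc))) {
    nl <- nine_locations(config$grid, rc[i, 1], rc[i, 2])
    for (y in pred_years) {
      nl$year <- y
      nl$period <- 14L        # growing-season scene
      g <- simulate_landsat_patches(art$truth, nl, config,
                                    heterogeneity = opt$heterogeneity,
                                    qa_bad_frac = opt$qa_bad_frac,
                                    seed = config$seed + 106L + i * 131L + y)
      if (length(g)) groups[[length(groups) + 1L]] <- g
    }
  }
  samples <- predict_reference_samples(models, groups, art$major_biome)
  list(pairs = pairs, models = models, samples = samples,
       locations = locs, n_groups = length(groups))
}

# Consistency-evaluation stage over the assembled product.
evaluate_stage <- function(art, config) {
  ev <- list()
  pairs <- match_product_to_points(art$product, art$ground)
  if (nrow(pairs) >= 2)
    ev$ground_validation <- regression_metrics(pairs$product, pairs$ground)
  ev$ground_pairs <- pairs
  ev$bias_product <- global_bias_series(art$product, art$truth)
  ev$bias_solely_artifact <- global_bias_series(art$solely_artifact, art$truth)
  ev$mission_trends_product <- suppressWarnings(
    mission_bias_trends(ev$bias_product, config$missions,
                        seed = config$seed + 201L))
  ev$mission_trends_artifact <- suppressWarnings(
    mission_bias_trends(ev$bias_solely_artifact, config$missions,
                        seed = config$seed + 202L))
  am <- annual_and_global_means(art$product, biome = art$major_biome)
  ev$annual_global <- am$global
  ev$trend_global <- mann_kendall_trend(am$global$fpar, am$global$year)
  ev$trends_by_period <- lapply(period_presets(), function(yrs) {
    sel <- am$global$year %in% yrs
    if (sum(sel) >= 4)
      mann_kendall_trend(am$global$fpar[sel], am$global$year[sel])
  })
  ev$iav_global <- interannual_variability(am$global$fpar)
  ev$decadal_trend <- decadal_nonlinear_trend(am$global$fpar,
                                              seed = config$seed + 203L)
  ev$hovmoller <- hovmoller_means(art$product, band_deg = 1,
                                  biome = art$major_biome)
  if (!is.null(art$reference) && nrow(art$reference$samples) > 0)
    ev$gridded <- gridded_comparison(
      list(product = art$product, solely_artifact = art$solely_artifact),
      art$reference$samples, cell_deg = 2,
      min_n = min(100L, max(3L, nrow(art$reference$samples) %/% 10L)))
  ev
}

# Write pipeline artifacts beneath outdir (scenes, indexes, tables).
finish_pipeline <- function(art, outdir) {
  if (is.null(outdir)) return(invisible(art))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(art$config, file.path(outdir, "config.yml"))
  if (!is.null(art$product))
    write_cube(art$product, file.path(outdir, "product"), "fpar",
               config_hash = art$config_hash, seed = art$seed)
  if (!is.null(art$samples))
    utils::write.csv(art$samples, file.path(outdir, "window_samples.csv"),
                     row.names = FALSE)
  if (!is.null(art$ground))
    utils::write.csv(art$ground, file.path(outdir, "ground_measurements.csv"),
                     row.names = FALSE)
  if (!is.null(art$reference) && nrow(art$reference$samples) > 0)
    utils::write.csv(art$reference$samples,
                     file.path(outdir, "reference_samples.csv"),
                     row.names = FALSE)
  if (!is.null(art$calibration)) {
    utils::write.csv(
      data.frame(pixel = seq_along(art$calibration$slope),
                 slope = as.vector(art$calibration$slope),
                 intercept = as.vector(art$calibration$intercept),
                 r = as.vector(art$calibration$r),
                 rmse = as.vector(art$calibration$rmse),
                 n = as.vector(art$calibration$n),
                 method = as.vector(art$calibration$method)),
      file.path(outdir, "pixel_calibration.csv"), row.names = FALSE)
  }
  if (!is.null(art$evaluation)) {
    ev <- art$evaluation
    utils::write.csv(ev$annual_global, file.path(outdir, "global_annual_fpar.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$bias_product, file.path(outdir, "bias_product.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ev$hovmoller),
                     file.path(outdir, "hovmoller.csv"))
    if (!is.null(ev$gridded) && nrow(ev$gridded))
      utils::write.csv(ev$gridded, file.path(outdir, "gridded_comparison.csv"),
                       row.names = FALSE)
  }
  invisible(art)
}
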