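test_that("patch quality screening applies the strict 90% and AOP rules", {
  base <- matrix(0.3, 20, 20)
  qa360 <- matrix(c(rep(TRUE, 360), rep(FALSE, 40)), 20, 20)
  expect_true(screen_patch_quality(manual_patch(base, qa = qa360)))   # 90.0%
  qa359 <- matrix(c(rep(TRUE, 359), rep(FALSE, 41)), 20, 20)
  expect_false(screen_patch_quality(manual_patch(base, qa = qa359)))
  # good coverage but excessive opacity still fails (conjunction)
  expect_false(screen_patch_quality(manual_patch(base, aop = 0.35)))
  expect_true(screen_patch_quality(manual_patch(base, aop = 0.3)))
})

test_that("patch aggregation is the masked mean over good pixels", {
  b <- matrix(0.42, 20, 20)
  expect_equal(unname(aggregate_patch_reflectance(manual_patch(b))),
               rep(0.42, 6))
  b2 <- matrix(runif(400), 20, 20)
  qa <- matrix(runif(400) > 0.3, 20, 20)
  p <- manual_patch(b2, qa = qa)
  got <- aggregate_patch_reflectance(p)
  expect_equal(unname(got), rep(mean(b2[qa]), 6), tolerance = 1e-12)
  expect_true(all(got >= min(b2[qa]) & got <= max(b2[qa])))
})

test_that("the CV filter matches hand arithmetic and is strict at 0.15", {
  hom <- manual_patch(matrix(0.3, 20, 20))
  res <- homogeneity_cv_filter(hom)
  expect_equal(unname(res$cv), rep(0, 6))
  expect_true(res$pass)
  # per-band CVs {0.1,0.1,0.1,0.2,0.2,0.2}: two alternating values a(1 +/- c)
  # have sample sd = a * c * sqrt(n/(n-1)), so c is chosen to land exactly
  n <- 400
  corr <- sqrt((n - 1) / n)
  cvs <- c(0.1, 0.1, 0.1, 0.2, 0.2, 0.2)
  bands <- array(0, c(20, 20, 6))
  for (k in 1:6) {
    cc <- cvs[k] * corr
    bands[, , k] <- matrix(0.4 * (1 + cc * rep(c(1, -1), 200)), 20, 20)
  }
  p <- manual_patch(bands)
  res2 <- homogeneity_cv_filter(p)
  expect_equal(unname(res2$cv), cvs, tolerance = 1e-12)
  expect_equal(res2$mean_cv, 0.15, tolerance = 1e-12)
  # strictness at the boundary: a threshold equal to the mean CV rejects
  expect_false(homogeneity_cv_filter(p, cv_max = res2$mean_cv)$pass)
  expect_true(homogeneity_cv_filter(p, cv_max = res2$mean_cv + 1e-9)$pass)
  # a 4-pixel fixture against the direct sd/mean oracle
  px <- c(0.2, 0.3, 0.4, 0.5)
  p4 <- manual_patch(matrix(px, 2, 2))
  expect_equal(unname(homogeneity_cv_filter(p4)$cv[1]), sd(px) / mean(px))
  # zero-mean band is undefined and fails
  zb <- manual_patch(matrix(0, 2, 2))
  expect_false(homogeneity_cv_filter(zb)$pass)
})

test_that("vegetation indices follow their standard formulas", {
  r <- c(blue = 0.05, green = 0.07, red = 0.3, nir = 0.3, swir1 = 0.2,
         swir2 = 0.15)
  vi <- vegetation_indices(r)
  expect_equal(unname(vi["ndvi"]), 0)
  expect_equal(unname(vi["evi2"]), 0)
  r2 <- c(blue = 0.25, green = 0.07, red = 0.1, nir = 0.5, swir1 = 0.2,
          swir2 = 0.15)
  vi2 <- vegetation_indices(r2)
  expect_equal(unname(vi2["ndvi"]), 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(unname(vi2["evi"]),
               2.5 * (0.5 - 0.1) / (0.5 + 6 * 0.1 - 7.5 * 0.25 + 1),
               tolerance = 1e-12)
  expect_equal(unname(vi2["evi2"]), 2.5 * 0.4 / (0.5 + 2.4 * 0.1 + 1),
               tolerance = 1e-12)
  expect_equal(unname(vi2["ndwi"]), 0.3 / 0.7, tolerance = 1e-12)
  # zero denominators leave the ratio indices undefined
  r3 <- c(blue = 0, green = 0, red = 0, nir = 0, swir1 = 0, swir2 = 0)
  vi3 <- vegetation_indices(r3)
  expect_true(is.na(vi3["ndvi"]))
  expect_true(is.na(vi3["ndwi"]))
})

test_that("the forest recovers a noiseless monotone target (OOB R2 >= 0.95)", {
  pairs <- forest_pairs(1500)
  mod <- train_reference_regressor(pairs, seed = 4)
  expect_gte(mod$oob$r2, 0.95)
  expect_equal(mod$forest$ntree, 200L)
  expect_equal(mod$forest$mtry, ceiling(14 / 3))
})

test_that("one regressor is trained per biome x sensor stratum, seeded", {
  pairs <- rbind(forest_pairs(120, biome = 1L, sensor = "TM", seed = 1),
                 forest_pairs(120, biome = 1L, sensor = "OLI", seed = 2),
                 forest_pairs(120, biome = 5L, sensor = "TM", seed = 3))
  mods <- train_reference_regressors(pairs, min_pairs = 100, seed = 9)
  expect_equal(length(mods), 3L)
  expect_setequal(names(mods), c("1.TM", "1.OLI", "5.TM"))
  mods2 <- train_reference_regressors(pairs, min_pairs = 100, seed = 9)
  expect_equal(mods[["1.TM"]]$oob$r2, mods2[["1.TM"]]$oob$r2)
  expect_error(train_reference_regressor(pairs, seed = 1), "single")
  # below the stratum minimum nothing is trained
  expect_equal(length(train_reference_regressors(pairs[1:50, ],
                                                 min_pairs = 100)), 0L)
})

test_that("a sample is emitted only when more than five locations survive", {
  pairs <- forest_pairs(300, biome = 1L, sensor = "TM")
  mods <- list("1.TM" = train_reference_regressor(pairs, seed = 2))
  g <- grid_spec(4, 4)
  bm <- uniform_biome(g, 1L)
  mk_group <- function(n_good) {
    lapply(seq_len(9), function(i)
      manual_patch(matrix(0.3 + 0.001 * i, 20, 20),
                   aop = ifelse(i <= n_good, 0.1, 0.9),
                   row = 2L, col = 2L, lat = 39.9, lon = -9.9))
  }
  out6 <- predict_reference_samples(mods, list(mk_group(6)), bm)
  expect_equal(nrow(out6), 1L)
  expect_equal(out6$n_locations, 6L)
  out5 <- predict_reference_samples(mods, list(mk_group(5)), bm)
  expect_equal(nrow(out5), 0L)
  expect_error(predict_reference_samples(mods, list(c(mk_group(9),
                                                      mk_group(1)[1])), bm),
               "nine")
})

test_that("same-half-month samples average across scenes", {
  pairs <- forest_pairs(300, biome = 1L, sensor = "TM")
  mods <- list("1.TM" = train_reference_regressor(pairs, seed = 2))
  g <- grid_spec(4, 4)
  bm <- uniform_biome(g, 1L)
  grp_a <- lapply(1:9, function(i) manual_patch(matrix(0.25, 20, 20),
                                                row = 3L, col = 3L))
  grp_b <- lapply(1:9, function(i) manual_patch(matrix(0.45, 20, 20),
                                                row = 3L, col = 3L))
  va <- predict_reference_samples(mods, list(grp_a), bm)$fpar
  vb <- predict_reference_samples(mods, list(grp_b), bm)$fpar
  both <- predict_reference_samples(mods, list(grp_a, grp_b), bm)
  expect_equal(nrow(both), 1L)
  expect_equal(both$fpar, mean(c(va, vb)), tolerance = 1e-12)
})

test_that("systematic random location sampling honors counts and the seed", {
  cfg <- tiny_config(nonveg_frac = 0, flip_frac = 0)
  bm <- generate_biome_map(cfg, 2010)
  avail <- table(factor(biome_name(bm$codes), levels = names(BIOME_CODES)))
  # request everything of one biome: all eligible cells are returned
  all_gra <- select_sample_locations(bm, c(GRA = unname(avail["GRA"])),
                                     seed = 1)
  expect_equal(nrow(all_gra), unname(avail["GRA"]))
  # the 0.7 ratio between DNF and other biomes is exact when cells suffice
  want <- min(10L, min(avail))
  locs <- select_sample_locations(bm, c(GRA = want,
                                        DNF = round(0.7 * want)), seed = 2)
  tab <- table(biome_name(locs$biome))
  expect_equal(unname(tab[["DNF"]] / tab[["GRA"]]), 0.7)
  locs2 <- select_sample_locations(bm, c(GRA = want,
                                         DNF = round(0.7 * want)), seed = 2)
  expect_identical(locs, locs2)
})

test_that("reference samples track the local truth in a synthetic world", {
  art <- acceptance_world()
  rs <- art$reference$samples
  expect_gt(nrow(rs), 10)
  expect_true(all(rs$n_locations >= 6))
  tv <- vapply(seq_len(nrow(rs)), function(i)
    art$truth$values[cube_scene_index(art$truth, rs$year[i], rs$period[i]),
                     rs$row[i], rs$col[i]], numeric(1))
  expect_gte(cor(rs$fpar, tv), 0.9)
})
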