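#!/usr/bin/env Rscript
# Stage 4: pixel-wise multi-sensor integration and splicing.
#
# Fits per-pixel overlap regressions of the benchmark on the solely record
# (OLS; penalized-spline smooths for evergreen broadleaf forest),
# back-calibrates the pre-2004 record, and assembles the spliced 1982-2022
# product. Writes the product as two-band scenes plus the calibration
# diagnostic maps.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "_common.R"))

art <- stage_artifacts("integrate")
d <- results_dir("product")

cal <- art$calibration
write.csv(data.frame(pixel = seq_along(cal$slope),
                     slope = round(as.vector(cal$slope), 5),
                     intercept = round(as.vector(cal$intercept), 5),
                     r = round(as.vector(cal$r), 4),
                     rmse = round(as.vector(cal$rmse), 5),
                     n = as.vector(cal$n),
                     method = c("identity", "linear", "smooth")[
                       as.vector(cal$method) + 1L]),
          file.path(d, "pixel_calibration.csv"), row.names = FALSE)
# scene TIFFs are bulky runtime artifacts; they go under scratch/ while the
# index and calibration tables stay with the results
scene_dir <- file.path("scratch", "product_scenes")
idx <- write_cube(art$product, scene_dir, "fpar",
                  config_hash = art$config_hash, seed = art$seed)
write.csv(idx, file.path(d, "scene_index.csv"), row.names = FALSE)

tab <- table(art$product$provenance)
message(sprintf("product: %d scenes (%s)", nrow(art$product$time),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
message(sprintf("calibration methods: %s",
                paste(c("identity", "linear", "smooth")[
                  as.integer(names(table(cal$method))) + 1L],
                  table(cal$method), sep = "=", collapse = ", ")))
message(sprintf("median overlap R %.3f, median overlap RMSE %.4f",
                median(cal$r, na.rm = TRUE), median(cal$rmse, na.rm = TRUE)))
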