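#!/usr/bin/env Rscript
# Stage 5: high-resolution FPAR reference samples.
#
# Selects pure constant-biome locations by systematic random sampling,
# simulates reflectance patches, screens them (90% good pixels, AOP,
# mean CV < 0.15), trains one 200-tree forest per biome x sensor stratum,
# and predicts reference samples wherever more than five of the nine
# locations in a coarse pixel survive.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "_common.R"))

art <- stage_artifacts("reference")
d <- results_dir("reference")

ref <- art$reference
write.csv(ref$samples, file.path(d, "reference_samples.csv"),
          row.names = FALSE)
oob <- do.call(rbind, lapply(names(ref$models), function(k)
  data.frame(stratum = k, n = ref$models[[k]]$n,
             oob_r2 = round(ref$models[[k]]$oob$r2, 4),
             oob_rmse = round(ref$models[[k]]$oob$rmse, 5))))
write.csv(oob, file.path(d, "forest_oob_metrics.csv"), row.names = FALSE)

message(sprintf("training pairs: %d over %d strata; %d forests trained",
                nrow(ref$pairs), length(unique(paste(ref$pairs$biome,
                                                     ref$pairs$sensor))),
                length(ref$models)))
message(sprintf("reference samples: %d from %d candidate pixel-scenes",
                nrow(ref$samples), ref$n_groups))
tv <- vapply(seq_len(nrow(ref$samples)), function(i)
  art$truth$values[cube_scene_index(art$truth, ref$samples$year[i],
                                    ref$samples$period[i]),
                   ref$samples$row[i], ref$samples$col[i]], numeric(1))
message(sprintf("correlation with local truth: %.3f",
                cor(ref$samples$fpar, tv)))
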