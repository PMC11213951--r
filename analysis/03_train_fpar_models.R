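#!/usr/bin/env Rscript
# Stage 3: window sampling and per-half-month neural regression.
#
# Extracts window samples over the 2004-2015 overlap (window 25, except 11
# for evergreen broadleaf forest), trains one network per half-month
# (70/15/15 split, seeded repetitions), and predicts the solely FPAR record
# from both NDVI variants.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "_common.R"))

art <- stage_artifacts("train")
d <- results_dir("models")

write.csv(art$samples, file.path(d, "window_samples.csv"), row.names = FALSE)
metrics <- do.call(rbind, lapply(art$models, function(m)
  data.frame(period = m$period, r2 = m$metrics$r2, rmse = m$metrics$rmse,
             mae = m$metrics$mae, mape = m$metrics$mape,
             val_rmse = m$val_rmse)))
write.csv(round(metrics, 5), file.path(d, "period_model_metrics.csv"),
          row.names = FALSE)

message(sprintf("window samples: %d (%d periods x %d overlap years)",
                nrow(art$samples), length(unique(art$samples$period)),
                length(unique(art$samples$year))))
message(sprintf("per-period test R2: min %.3f / median %.3f / max %.3f",
                min(metrics$r2), median(metrics$r2), max(metrics$r2)))
message(sprintf("solely record: %d scenes from the drift-corrected NDVI",
                nrow(art$solely$time)))
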