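#!/usr/bin/env Rscript
# Stage 6: the consistency-evaluation suite.
#
# Direct validation against the ground network, de-seasonalized bias with
# per-mission EEMD trends for the assembled product and for the record
# built from the artifact-laden NDVI, gridded comparison against the
# reference samples, annual and global means with Mann-Kendall trends over
# the conventional periods, decadal nonlinear trend, interannual
# variability, and Hovmoller band means.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "_common.R"))

art <- stage_artifacts("evaluate")
ev <- art$evaluation
d <- results_dir("evaluation")

write.csv(ev$annual_global, file.path(d, "global_annual_fpar.csv"),
          row.names = FALSE)
write.csv(ev$bias_product, file.path(d, "bias_product.csv"), row.names = FALSE)
write.csv(ev$bias_solely_artifact, file.path(d, "bias_solely_artifact.csv"),
          row.names = FALSE)
write.csv(as.data.frame(ev$hovmoller), file.path(d, "hovmoller.csv"))
if (!is.null(ev$gridded) && nrow(ev$gridded))
  write.csv(ev$gridded, file.path(d, "gridded_comparison.csv"),
            row.names = FALSE)

trend_tab <- do.call(rbind, lapply(names(ev$trends_by_period), function(p) {
  tr <- ev$trends_by_period[[p]]
  if (is.null(tr)) return(NULL)
  data.frame(period = p, slope = tr$slope, sen = tr$sen_slope,
             mk_z = tr$z, mk_p = tr$p, stars = tr$stars)
}))
write.csv(trend_tab, file.path(d, "trends_by_period.csv"), row.names = FALSE)

jump_tab <- rbind(
  cbind(record = "product", ev$mission_trends_product$jumps),
  cbind(record = "solely_artifact", ev$mission_trends_artifact$jumps))
write.csv(jump_tab, file.path(d, "era_boundary_jumps.csv"), row.names = FALSE)

message("direct validation against ground sites:")
print(ev$ground_validation)
message("global trend (full period):")
print(ev$trend_global)
mean_fpar <- mean(art$product$values, na.rm = TRUE)
rng <- function(mt) max(vapply(mt$trends, function(x) max(abs(x$trend)),
                               numeric(1)))
message(sprintf("bias trend, %% of mean FPAR: product %.2f%% vs artifact record %.2f%%",
                100 * rng(ev$mission_trends_product) / mean_fpar,
                100 * rng(ev$mission_trends_artifact) / mean_fpar))
message(sprintf("largest era-boundary jump: product %.4f vs artifact record %.4f",
                max(abs(ev$mission_trends_product$jumps$jump)),
                max(abs(ev$mission_trends_artifact$jumps$jump))))
message(sprintf("interannual variability (sd of detrended anomalies): %.5f",
                ev$iav_global))
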