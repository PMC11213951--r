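#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study world.
#
# Builds the regional 1/12-degree tile (60 x 120 cells, 1982-2022): yearly
# biome maps and their 20-year majority map, the FPAR truth, two NDVI
# variants (drift-corrected and artifact-laden), the noisy benchmark FPAR
# record, and a ground-site network.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "_common.R"))

cfg <- analysis_config()
d <- results_dir("world")
write_config(cfg, file.path(d, "config.yml"))

art <- stage_artifacts("simulate")

write.csv(art$ground, file.path(d, "ground_measurements.csv"),
          row.names = FALSE)
shares <- table(biome_name(art$major_biome$codes))
write.csv(data.frame(biome = names(shares), cells = as.integer(shares)),
          file.path(d, "biome_shares.csv"), row.names = FALSE)

message(sprintf("world: %d x %d cells, %d truth scenes, %d NDVI scenes, %d ground obs",
                cfg$grid$nrow, cfg$grid$ncol, nrow(art$truth$time),
                nrow(art$ndvi_clean$time), nrow(art$ground)))
message(sprintf("mission eras: %s",
                paste(cfg$missions$mission, cfg$missions$start,
                      cfg$missions$end, collapse = " | ")))
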