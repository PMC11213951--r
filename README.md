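# fparcdr

Construction and consistency evaluation of a long-term half-monthly FPAR
climate data record from NDVI.

## The problem

FPAR — the fraction of photosynthetically active radiation (400–700 nm)
absorbed by the vegetation canopy, dimensionless in [0, 1] — is an
essential climate variable. The only observations long enough for
multi-decadal vegetation analysis come from the AVHRR satellite series,
whose orbital drift, sensor degradation and platform replacements imprint
spurious ramps and jumps on any record regressed naively from them.

`fparcdr` builds a temporally consistent 1982–2022 FPAR record the way
modern harmonized products are built, and then audits it:

1. **Solely record** — per half-month, a single-hidden-layer network maps
   (NDVI, window-center coordinates, biome) to a benchmark FPAR climate
   data record. Training samples are medians over N × N spatial windows
   restricted to *dominant* biomes (> 10 % of valid pixels; window 25,
   except 11 for evergreen broadleaf forest), split 70/15/15, with
   hyperparameters found by Gaussian-process sequential search over
   repetition-averaged validation RMSE.
2. **Integration** — per pixel, the benchmark is regressed on the solely
   record over the 2004–2015 overlap (OLS; a penalized-spline smooth for
   evergreen broadleaf forest), the pre-2004 record is back-calibrated,
   and the calibrated early record is spliced with the benchmark into one
   984-scene product with per-scene provenance.
3. **Evaluation** — direct validation against ground sites; de-seasonalized
   bias with per-mission-era nonlinear trends by ensemble empirical mode
   decomposition (EEMD, noise 0.2, ensemble 100); 2°-gridded comparison
   against high-resolution reference samples produced by per-biome-and-
   sensor random forests (200 trees, ⌈14/3⌉ split candidates, minimum leaf
   5, out-of-bag metrics); Mann–Kendall trend tests on cos-latitude-
   weighted annual means; decadal EEMD trends; interannual variability;
   Hovmöller band means.

Everything runs offline against a **synthetic world** — a seeded generator
producing the NDVI source (with and without per-era drift ramps and
boundary jumps), the benchmark, biome maps, reflectance patches and ground
sites with known truth — so every stage is testable end to end. See the
methods vignette (`vignettes/fpar-record-construction.Rmd`) for the model,
parameter meanings and design choices.

## Worked example

A desk-scale world (20 × 40 cells at 1/12°, full 1982–2022 span):

```r
library(fparcdr)

cfg <- world_config(nrow = 20, ncol = 40, seed = 1)
art <- run_pipeline(cfg, stages = "all", verbose = FALSE)

art$product
#> <raster_cube> fpar: 984 scenes (1982-2022), 20 x 40 cells at 0.0833 deg
#>   fill: 12.4%  qc-good: 87.6%
table(art$product$provenance)
#> benchmark calibrated
#>       456        528

art$evaluation$ground_validation
#> R2 = 0.9537  RMSE = 0.0510  MAE = 0.0407  MAPE = 10.51%  (n = 4690)

art$evaluation$trend_global
#> slope = 0.000417 yr^-1 (Sen 0.000414), MK S = 808, z = 9.06, p = 1.26e-19 ***
```

The product is a 41-year record: 528 scenes back-calibrated from the
solely record, 456 sourced from the benchmark after the 2004 splice.
Ground validation pairs the product with site measurements averaged per
cell and half-month. The recovered global trend (4.2 × 10⁻⁴ yr⁻¹,
Mann–Kendall p ≪ 0.001) matches the 5 × 10⁻⁴ yr⁻¹ injected into the
synthetic truth up to masking and clipping effects.

The point of the exercise is the drift contrast:

```r
ev <- art$evaluation
mean_fpar <- mean(art$product$values, na.rm = TRUE)
rng <- function(mt) max(sapply(mt$trends, function(d) max(abs(d$trend))))
100 * rng(ev$mission_trends_product) / mean_fpar    # assembled product
#> [1] 0.41
100 * rng(ev$mission_trends_artifact) / mean_fpar   # drift-laden record
#> [1] 15.49
```

The assembled product's de-seasonalized bias against truth stays flat
(per-era EEMD trend about 0.4 % of mean FPAR), while the record regressed
from the artifact-laden NDVI variant swings by about 15 % and jumps at
every platform change — the synthetic restatement of how a harmonized
record is distinguished from a conventional AVHRR-based one.

## Analysis workflow

The numbered drivers under `analysis/` run the same pipeline at the full
default tile (60 × 120 cells) stage by stage, narrating what each found
and writing tables under `results/`:

```sh
Rscript analysis/01_simulate_world.R        # the synthetic study world
Rscript analysis/02_preprocess_benchmark.R  # 3-sigma weights + weighted SG filter
Rscript analysis/03_train_fpar_models.R     # window samples + 24 period networks
Rscript analysis/04_integrate_records.R     # pixel-wise calibration + splice
Rscript analysis/05_reference_samples.R     # forests + reference samples
Rscript analysis/06_evaluate_consistency.R  # the full evaluation suite
```

Stages cache under `scratch/` (delete it for a clean rebuild); product
scenes are written as two-band TIFFs (value + QC, scaled-integer encoding,
JSON sidecars with geotransform, provenance, config hash and seed) with a
scene index CSV.

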