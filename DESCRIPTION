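Package: fparcdr
Title: Construction and Consistency Evaluation of a Long-Term FPAR Climate Data Record
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a temporally consistent, half-monthly record of the fraction
    of absorbed photosynthetically active radiation (FPAR) from a quality-
    controlled NDVI source and a benchmark FPAR climate data record, and runs a
    full consistency-evaluation suite on the result. The pipeline covers
    weighted Savitzky-Golay smoothing with one-sided outlier down-weighting,
    maximum-value compositing to a 24-period half-month calendar, spatial-window
    sampling with dominant-biome selection, per-period neural regression from
    NDVI and location to FPAR with sequential model-based hyperparameter search,
    pixel-wise multi-sensor integration (ordinary least squares, with penalized-
    spline smooths for evergreen broadleaf forest), generation of high-
    resolution FPAR reference samples via per-biome-and-sensor random forests,
    and evaluation diagnostics: de-seasonalized bias with per-mission ensemble
    empirical mode decomposition trends, gridded product comparison,
    Mann-Kendall trend testing, interannual variability, and Hovmoller band
    means. A synthetic-world generator emulates all required inputs, including
    per-mission orbital-drift and platform-change artifacts, so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    randomForest,
    mgcv,
    kernlab,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
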