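Package: ctcforce
Title: Nanomechanical and Capture Analysis of Microfluidically Isolated Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for atomic force microscopy (AFM) force-volume analysis of
    captured circulating tumor cells and for the surrounding microfluidic
    capture assay. Processes approach/retraction force-distance curves
    (baseline and contact-point estimation, Hertz contact-model fits of the
    Young's modulus, deformation at maximum load, adhesion rupture-event
    detection with a nearest-neighbor minimum rule, trapezoidal work of
    detachment), aggregates per-pixel results into population summaries with
    lognormal or Gaussian density fits and Welch t tests, quantifies
    fluorescence images (integrated density and corrected total fluorescence
    with mean/SD intensity transfer), and computes cell-capture metrics
    (capture efficiency, purity, white-blood-cell background density,
    log-log spike-in recovery regression, per-milliliter CTC aggregation).
    A seeded synthetic-data module generates Hertzian force curves,
    force-volume grids, fluorescence rasters, and capture experiments so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
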