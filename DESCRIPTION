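Package: socmap
Title: Pixel-Scale Soil Organic Carbon Mapping from Laboratory
    Hyperspectral Images
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map soil organic carbon (SOC) at pixel resolution
    down undisturbed soil cores from laboratory VNIR hyperspectral
    imaging. Implements reflectance-target normalization, band-ratio
    masking of non-soil components, standard normal variate (SNV)
    spectral transformation, region-of-interest calibration with
    chemometric regression (partial least squares, random forest,
    support vector machine), calibration-range constraints and
    depth-stratified bias correction of the predicted maps, bulk-sample
    model evaluation (ME, RMSE, MAE, RPD, R-squared, including
    plus/minus one standard deviation variants), equal-area depth
    profiles, and detection and quantification of SOC hotspots such as
    subsoil biopores. A synthetic soil-core generator with a forward
    spectral model provides ground-truth data so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    png
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
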