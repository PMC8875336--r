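Package: grazint
Title: Spatial-Temporal Grazing Intensity from GPS Collar Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the spatial-temporal distribution of sheep
    grazing intensity from GPS collar fix streams. Provides kernel-density
    clustering of track points with five-grade classification and exclusion
    of rest and drinking zones, constant-rate intake allocation onto a
    square analysis grid using rectangular segment buffers, terrain and
    vegetation covariate extraction (NDVI, slope, aspect, elevation), and a
    from-scratch feedforward neural network with backpropagation for
    screening feature-subset combinations against allocated intensity.
    Includes a synthetic trajectory and raster generator that emulates the
    statistical structure of a grazing day (pen departure and return, rest
    and drinking clusters, NDVI-biased grazing loops) with a planted
    ground-truth intake field for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    nnet
Config/testthat/edition: 3
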