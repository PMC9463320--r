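Package: monoloc
Title: Monoplane X-Ray 3D Device Localization Using Vascular Centerline
    Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Localizes interventional devices in 3D from a single monoplane
    X-ray fluoroscopy projection by combining a calibrated C-arm camera
    model with a co-registered vascular centerline tree: the centerline
    point whose projection ray is most parallel to the device's
    back-projection ray (a cross-product objective) is selected as the 3D
    position, optionally restricted to the geodesic neighborhood of the
    previous position to enforce continuous device motion.  Includes
    fiducial-based rigid/similarity/affine point-set registration,
    two-view epipolar triangulation for reference reconstructions,
    normalized cross-correlation template tracking of device markers
    across frame sequences, a parametric aortic-arch phantom generator
    with controlled marker offsets, and the 3D/2D Euclidean-distance
    error metrics used to evaluate such methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
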