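Package: fracdim3d
Title: Fractal Dimension of 3-D Binary Segmentations by Box Counting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the box-counting (Minkowski-Bouligand) fractal
    dimension of 3-D binary voxel segmentations such as cortical ribbon
    masks.  Counts occupied grid cells across dyadic spatial scales with
    random grid-origin offsets, fits the log-log power law by ordinary
    least squares, and selects the interval of fractal spatial scales by
    one of four strategies: a fixed a-priori range, a bounding-box
    derived range, the interval maximising the adjusted coefficient of
    determination, or an improved selection by rounded adjusted R-squared
    with a widest-interval tie-break.  Includes generators for voxel
    phantoms with analytically known dimension (cube, plane, Menger
    sponge, perturbed spherical shell) and an evaluation layer for
    brain-age studies: Pearson association of a morphometric feature
    with age and individual age prediction by linear regression in
    repeated cross-validation with permutation significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
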