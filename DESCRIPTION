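Package: junctmorph
Title: Morphometry of Membrane Junction Necks from Triangulated Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional geometry of
    membrane junctions segmented from electron tomograms: stitching traced
    contour stacks into triangulated surfaces, cross-sectioning meshes
    along an adaptive centreline, locating the constricted neck as the
    minimum-area cross-section, and measuring junction width, aspect ratio
    and length from minimum-area rotated bounding rectangles. Includes
    specimen-shrinkage correction, nuclear-envelope surface-area and
    junction-frequency estimation, stereological sampling of inspection
    regions on segmented nuclear surfaces, and a synthetic-geometry
    generator (hyperboloid hourglass necks, wide cones, envelope sheets,
    ellipsoidal nuclear masks) with closed-form ground truth for
    validation.
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
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
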