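---
title: "Measuring membrane junction necks on triangulated surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring membrane junction necks on triangulated surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctmorph)
```

## The measurement problem

Junctions between the endoplasmic reticulum (ER) and the outer nuclear
membrane are three-dimensional membrane funnels a few tens of nanometres
across. Electron tomography delivers them as manually traced contour
stacks that are stitched into triangulated surfaces. Comparing junction
shapes across cells and cell-cycle stages needs numbers, not pictures:
a width, an aspect ratio and a length per junction, each defined
operationally on the mesh so that two analysts (or two labs) compute the
same value. junctmorph implements that operational definition, the
abundance estimates built on top of it, and a synthetic-geometry
generator that provides ground truth for every stage.

## The per-junction procedure

Given a junction mesh, an annotated base point (where the junction meets
the mean plane of the outer nuclear membrane) and an axis hint pointing
into the junction:

1. **Section series.** The mesh is cut by planes at fixed arc-length
   stations (default every 0.5 nm) from the base. In the default
   adaptive mode the next plane origin is the previous section's
   centroid advanced along the current axis; the axis is re-estimated
   from the smoothed centroid track so the series follows bent necks.
2. **Neck.** The neck is the cross-section with the smallest area within
   25 nm of the base; ties go to the station nearer the base. If the
   smallest section is the first one and areas increase monotonically,
   the junction has no interior constriction and is flagged
   `non_constricted` — the wide-cone geometry typical of junctions
   within the ER network, as opposed to the constricted hourglass.
3. **Width and aspect ratio.** The neck's top profile gets a
   minimum-area *rotated* bounding rectangle (rotating calipers on the
   convex hull), so tilted profiles are not penalised. Width is the mean
   of the rectangle's sides; the aspect ratio is their quotient.
4. **Length.** From the neck outward in both directions, the nearest
   sampled station whose area reaches 1.2 times the neck area marks the
   end of the constricted region; `L1` (envelope side) and `L2` (ER
   side) sum to `L`. A side that ends before reaching the threshold —
   a junction truncated at the tomogram border — is reported `NA` and
   flagged, and such junctions are excluded from summary means.
5. **Native scale.** Chemical sample preparation shrinks the specimen
   linearly by a calibrated 17%; `correct_shrinkage()` divides measured
   dimensions by `1 - 0.17`. A measured width range of 7–20 nm therefore
   corresponds to 8–24 nm native, and a 4–15 nm length range to 5–18 nm.

```{r}
j <- make_hourglass(junction_spec(neck_diameter = 20, neck_scale = 10,
                                  mesh_step = 0.5))
m <- measure_junction(j$mesh, j$base_point, j$axis,
                      shrinkage_fraction = 0.17)
m
```

The hyperboloid ground truth for this fixture is a width of 20 nm and a
length of `2 * 10 * sqrt(0.2)` = 8.94 nm.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `step` | 0.5 | nm | station spacing; bounds the length discretisation error at half a step per side |
| `window` | 25 | nm | how far from the base the neck may sit |
| `factor` | 1.2 | — | area ratio ending the constricted region |
| `shrinkage_fraction` | 0.17 | — | calibrated linear specimen shrinkage |
| `mode` | adaptive | — | centreline follows section centroids; `fixed` keeps the annotated axis |
| `smooth_window` | 13 | vertices | loop denoising before the rectangle fit |
| `min_convexity` | 0.3 | — | rejects slice artefacts that are not transversal profiles |

Station arithmetic runs along the arc length of the centreline polyline,
not the straight axis, and the neck window is measured the same way.
The tie rule for two equal area minima (nearest the base) and the
nearest-sampled-station convention for the 1.2-fold rule (no
interpolation) are both explicit so the procedure is reproducible.

## Numerical choices

**Loop smoothing and the rectangle's noise bias.** A bounding rectangle
is an extreme-value statistic: independent vertex noise only ever makes
it larger. On meshes with sub-nanometre tracing jitter this inflates
widths by 1–2 nm. Each section loop is therefore smoothed with a short
circular moving average (13 vertices, capped at 1/8 of the loop's vertex
count) before the rectangle fit, and the averaging gain on the loop's
fundamental harmonic is compensated by rescaling about the centroid so
smoothing does not shrink a clean loop. On noiseless fixtures the
residual width error is below 0.3%; with 0.5 nm vertex jitter the
remaining bias is about +0.3 nm.

**Adaptive axis stability.** Re-estimating the centreline direction from
a single centroid step feeds centroid noise and plane-tilt feedback into
the next section and oscillates on steep flares (an oblique cut through
a converging flare reads falsely small). The direction is instead taken
over a five-section centroid baseline and applied with a low gain (30%
of the residual angle per step, capped at 15 degrees). A 90-degree bent
tube is tracked with section areas constant to ~1%, while a fixed axis
diverges on the same fixture.

**Section quality.** A plane grazing a nearly coplanar, noisy sheet
(the envelope annulus at the junction base) chains into self-crossing
loops whose shoelace area nearly cancels while their bounding rectangle
stays large. Candidate loops must be closed, enclose the current
centreline point, and have a loop-area to rectangle-area ratio of at
least 0.3 (a true transversal profile sits near pi/4). The plane through
the base itself is degenerate in the synthetic scenes (it contains the
envelope sheet), so a series silently starts at the first station with a
qualifying loop.

**Contour stitching.** Consecutive traced contours are joined by a
greedy zipper that advances on whichever side keeps the new diagonal
shorter. A literal smallest-added-triangle rule degenerates on finely
sampled contour pairs — the side with shorter steps always adds the
smaller triangle and laps the other contour — whereas the
shortest-diagonal rule is self-correcting and reproduces analytic
cylinder, frustum and spherical-cap band areas to better than 1%.

## Abundance and stereology

Junction frequency is the deduplicated junction count divided by the
screened envelope area. The envelope area can be computed two ways —
stitching the traces into a mesh, or summing trace length times depth
per region — and the two agree to within ~3% on near-flat regions,
which the test suite checks on synthetic sheets. Counts include
junctions of ambiguous lumen class; contact-site records (membranes not
continuous) are tallied but never counted as junctions nor measured.

```{r}
f <- junction_frequency(23, 178)   # 23 junctions over 178 um^2 screened
f
estimate_total(f, 800)             # typical interphase envelope, 800 um^2
```

Frequencies are reported to two decimals (round half to even) and
per-nucleus totals to one significant figure; the unrounded values are
always kept alongside, and a truncated two-decimal variant is also
emitted because a count of 21 over 112 um^2 (0.1875 um^-2) prints as
0.18 only under truncation. Both conventions are exposed rather than
asserting one.

For whole-cell volumes, `make_nuclear_mask()` builds ellipsoidal binary
masks, `extract_surface()` takes the six-connected boundary in world
(nm) coordinates so anisotropic voxels are safe, and
`sample_surface_points()` spreads inspection points by farthest-point
sampling after a seeded random start — one operational reading of
"one random point, the rest distributed uniformly", and a reproducible
one. Spherical ROIs are cut with exact centre-distance membership
(a sub-voxel radius still returns the voxel containing the centre), and
`screen_report()` tallies findings per ROI and junction kind.

## The synthetic generator, and what it does not emulate

`make_hourglass()` builds a hyperboloid of revolution,
`r(s) = r0 * sqrt(1 + s^2/c^2)`, optionally scaled to an elliptical
cross-section, blended into a flat envelope annulus at the base and left
open at the ER side. The family was chosen because it is a smooth
hourglass with closed forms for everything the pipeline measures: width
`r0 * (1 + ellipticity)`, aspect ratio `ellipticity`, and length
`2c * sqrt(0.2)` under the 1.2-fold rule. `make_wide_cone()` provides
the contrasting non-constricted geometry. Junctions without a resolvable
lumen are the same surface family with the neck diameter near the lipid
bilayer thickness (~6.9 nm), since traces follow the bilayer midline.
Tracing noise is modelled as isotropic Gaussian vertex jitter after
tessellation; truncated junctions are produced by clipping the mesh with
a plane. `sample_population()` draws neck diameters from a normal
distribution truncated at 2 nm (defaults 17.4 +/- 5.0 nm, the
lumen-class interphase values) and places junctions uniformly on a
square envelope sheet.

What the generator deliberately does not emulate: image formation (tilt
series, missing wedge, detector noise), segmentation errors that are
correlated along a trace, membrane thickness (surfaces are the bilayer
midline), crowding or spatial clustering of junctions, and envelope
curvature at the junction scale. Passing the recovery tests therefore
shows that the geometry pipeline is unbiased on clean and
vertex-jittered geometry of known shape — not that segmentations of real
tomograms are error-free.

## Problem sizes used in the tests

The test suite and the acceptance script run populations of 100
synthetic junctions at 1 nm tessellation with 0.5 nm sections (about
15–20 s), single high-resolution fixtures at 0.5 nm tessellation, and
nuclear masks of about 100^3 voxels. These sizes keep every analytic
check comfortably resolved (tessellation error below tracing noise)
while the whole suite completes in a few minutes.

## Known limitations

* The centreline is defined by the adaptive centroid rule; profoundly
  kinked or branching junctions are out of scope.
* `contours_to_mesh()` assumes consecutive contours overlap in
  projection and refuses ambiguous correspondences instead of guessing.
* The 1.2-fold length uses the nearest sampled station (by design, to
  match the operational definition); the discretisation error is bounded
  by the station step, not by interpolation accuracy.
* Mesh I/O reads and writes ASCII OBJ/PLY/STL only; binary variants of
  those formats are rejected with an explicit error.
* The summary conventions (two-decimal frequencies, one-significant-
  figure totals) are reporting choices, not statistical claims.
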