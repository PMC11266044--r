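---
title: "From tile images to whole-brain volumes: the BrainMosaic methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tile images to whole-brain volumes: the BrainMosaic methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainMosaic)
```

## The problem

Serial two-photon tomography (TissueCyte-style block-face imaging)
alternates two-photon imaging of an optical plane below the cut surface
with vibratome sectioning. Each optical section is acquired as a grid of
overlapping camera tiles — typically an 11 x 14 grid of 832 x 832-pixel,
16-bit tiles per channel, four channels per section, 280 or so sections per
mouse brain. Because the block face never moves between cuts, sections come
out pre-aligned in z; the whole reconstruction problem is in-plane: remove
per-tile optics artifacts (vignetting, lens distortion), find where each
tile sits on the section canvas, blend the overlaps seamlessly, and stack
the sections into a 3D volume with correct physical spacing.

BrainMosaic implements that pipeline end to end, together with a
synthetic-acquisition generator that provides ground truth for every stage.
Everything below is exercised by the test suite and by
`scripts/acceptance.R`; this vignette explains the models, their knobs, and
the design decisions.

## Flat-field (vignetting) correction

Lens vignetting makes tile centers brighter than edges, which shows up as a
periodic brightness pattern across a naive mosaic. The correction model is
deliberately empirical: the *profile* of a channel is the per-pixel
arithmetic mean over many tiles of that channel (`computeProfile()`).
Averaging cancels the tissue content and leaves the smooth illumination
field, and `normalizeTile()` divides each tile by its profile pixel by
pixel.

Choices that matter:

* **Scope.** The default profile averages tiles from the whole brain
  (`profileScope = "brain"`); a per-section option exists. Per-brain
  averaging uses two orders of magnitude more tiles, so labeled cells —
  which are bright but sparse — contribute almost nothing to the mean.
  With few tiles the profile retains cell residue and normalization
  imprints inverted ghosts of it; the end-to-end test works at 16 tiles
  with moderate cell contrast for exactly this reason.
* **No clamping.** Normalized values are *not* clipped to [0, 1]: tissue
  background lands near 1 and labeled somata stay several times brighter,
  which is the signal downstream counting needs. Intensities return to the
  storage regime only when a stitched section is written, via a rescale
  factor that defaults to the profile's global mean.
* **Epsilon.** The division floor is `max(1e-6, 1e-3 * mean(profile))`. It
  only engages at dead pixels; an all-zero placeholder tile divides to an
  all-zero tile rather than NaN.

What a flat fixture shows: for tiles that are a constant field times a
known radial gain, normalization drives the mosaic coefficient of variation
from the gain contrast (~8% at `edgeGain = 0.6`) to numerical zero. Real
tissue is not flat, so the honest claim is the fixture's: the *illumination
component* is removed; minor tiling effects from non-illumination sources
can remain.

## Lens-distortion calibration

Distortion is calibrated once per instrument from an image of an EM mesh
grid (a target of known pitch with orthogonal bars) and then reused for all
tiles, channels, sections and brains scanned on that machine — the fixture
tests verify that recalibrating from the same grid image is bit-identical.

The calibration chain in `calibrateDeformation()`:

1. **Corner detection** (`detectGridCorners()`). Otsu threshold, connected
   components of the grid holes, discard components touching the image
   border (partial cells carry insufficient information) and sub-sized
   specks, intensity-weighted centroids, and finally each interior cell
   corner as the mean of its four surrounding hole centroids. The
   mean-of-four construction cancels first-order local distortion, which is
   why it is subpixel-accurate (~0.1 px RMS on synthetic grids) despite
   being simple; we chose it over fitting bar centerlines because it has no
   line-fit failure modes and is exactly deterministic. The grid must be
   roughly axis-aligned; hole binning uses the expected pitch.
2. **Template.** An ideal, exactly equally spaced lattice with the same
   node counts, pitch fixed to the target's nominal pitch, origin chosen so
   both lattices share their centroid (keeping the corrected image inside
   the frame).
3. **Homography.** A normalized-DLT least-squares projective fit from
   detected corners to template corners; exact relations are recovered to
   ~1e-12.
4. **Residual spline.** What the global projective model cannot express is
   captured per node as `template - projected` and interpolated by one C2
   natural bicubic spline anchored on the template lattice
   (`fitResidualSpline()`). A bicubic spline through a net of Bezier
   control patches is the same surface in a different basis; we implement
   the spline directly. Node displacements are reproduced exactly; between
   nodes the surface is bicubic, and beyond the lattice hull the field is
   extended by clamped (constant) extrapolation — the conservative choice,
   since extrapolated polynomials diverge.
5. **Dense lookup.** For each corrected pixel `t` the source coordinate is
   the closed form `H^-1 (t - D(t))`; at every template node this lands
   exactly on the detected corner, so no iterative inversion is needed. The
   lookup is compiled once per tile shape and serialized (JSON header plus
   raw float64 payload, gzipped) for bit-exact reuse.

Application (`applyCorrection()`) is inverse mapping with bilinear
interpolation; out-of-bounds sources take the nearest edge pixel (no
ringing, bounded values). An identity model is a bit-exact no-op and
constants stay constant.

Measured on synthetic warps of amplitude up to 5 px: re-detected corners of
the corrected grid sit within 0.2–0.35 px RMS of the ideal lattice, and a
warped phantom is recovered to ~0.3% mean error of the dynamic range on the
interior. One measurement subtlety: correction can push border cells into
or out of the frame, so the residual is computed against the ideal grid
extended periodically — otherwise a newly revealed corner row, correct to a
tenth of a pixel, would be scored as a full-pitch error against the finite
template.

## Inter-tile translation estimation

The stage moves a fixed step between tiles, so the tile-to-tile offset is a
global constant pair (one step per axis, plus a small perpendicular drift),
stable across sections and scans; it is estimated once and reused. For a
horizontal pair, a 100-px strip from the leading tile's right edge and a
50-px strip from the trailing tile's left edge are compared under
normalized cross-correlation (`nccSurface()`, the textbook
mean-and-variance-normalized form, values in [-1, 1]); the integer argmax
gives the step. Vertical pairs are the same computation transposed.
`estimateTranslationParams()` aggregates many pairs by the per-direction
median, which tolerates up to half the pairs being corrupted.

Choices that matter:

* **Integer placement.** Tiles are placed pixel by pixel, so estimates are
  integer; a parabolic subpixel refinement would change placement by less
  than the blending ramp and is deliberately absent.
* **Search geometry.** The detectable overlap range is
  `[narrowStrip, wideStrip]`, so strip widths must bracket the true
  overlap; the pipeline derives them from the metadata's nominal overlap
  with drift headroom. The perpendicular search is ±10 px by default.
* **Tie-breaks and confidence.** Equal-correlation ties resolve toward the
  nominal overlap, then toward zero drift, making the estimator
  deterministic. Pairs whose peak falls below 0.3 are excluded: a flat
  (zero-variance) strip is defined to correlate at 0, so featureless pairs
  never vote. On faint, smooth-textured tissue the peak itself — not the
  argmax — is what fails first: with tile noise at 5% of the dynamic range
  the correlation of a weak-contrast overlap drops below the floor even
  when the argmax is still correct. The recovery property is therefore
  stated for texture whose contrast clears the floor under that noise, and
  in the pipeline the estimation runs after normalization and distortion
  correction: uncorrected warp displaces the two sides of an overlap by
  different amounts (that is precisely the stitching artifact being
  corrected) and biases the step by several pixels.

## Stitching and blending

`computeTilePositions()` is pure arithmetic:
`y0 = margin + row * step_y + col * dy_h`,
`x0 = margin + col * step_x + row * dx_v`, validated against the canvas
dimensions from the section metadata (the implied canvas is
`2 * margin + (n - 1) * step + tile` per axis; a metadata disagreement
warns and the metadata wins, an out-of-canvas placement is an error).
With the whole-brain defaults — 832-px tiles, an 11 x 14 grid, steps
(788, 800), a 2-px margin per side — the arithmetic reproduces a
8,716 x 11,236-px section canvas.

`stitchSection()` resolves overlaps without trimming: every output pixel is
a convex combination `sum(w_i tile_i) / sum(w_i)` of the covering tiles.
The default weight ramps linearly from the tile edge to 1 at the overlap
depth ("feathering"); plain averaging is available as `blend = "mean"`.
Feathering and averaging agree at the overlap midline, but feathering
removes the step that plain averaging leaves where a tile's edge crosses
the interior of its neighbor. Two exact consequences are tested: a pixel
covered by one tile keeps that tile's value, and slicing a phantom and
restitching at ground truth reproduces it to 1e-6 in the float path.
Missing tiles participate as zero placeholders — a documented dark region
rather than a hole or a crash.

## 2D to 3D

`stackSections()` orders stitched sections by index (never arrival order),
refuses gaps unless told to zero-fill, and records physical spacing —
(50, 1.25, 1.25) um for (z, y, x) under the default acquisition.
`writeNiftiVolume()` stores the array in NIfTI's (x, y, z) order with the
spacing in millimetres in the header; the affine is the scaled identity.
The anatomical orientation is deliberately uncalibrated: the z axis is the
sectioning order as imaged (the specimen is mounted cerebellum-up), and no
claim is made about left/right until a registration step outside this
package's scope assigns one.

`downsampleVolume()` uses block means with per-axis integer factors nearest
to `target / source`; the 10-um and 50-um in-plane defaults match the
resolutions the Allen CCF reference space is distributed at, which is what
downstream registration consumes.

`writeOmeZarr()` emits an OME-NGFF 0.4 multiscale group. Since no R Zarr
client is available to this package, a minimal Zarr v2 writer/reader is
included (raw uncompressed chunks, C order, "." separator) — enough for any
conforming reader, including Neuroglancer, to consume. Intensities are
exposure-rescaled so the (0.5, 99.5) percentiles span the dtype range
(percentiles chosen as a conventional robust-stretch default), level 0
stores the rescaled voxels, and each level halves y and x by block
averaging of the stored (integer) parent level, so every level is exactly
reproducible from level 0. `viewerUrl()` encodes a Neuroglancer state with
a zarr-type layer pointing at the store; it is a pure string function,
deterministic by construction.

## The synthetic acquisition generator

The fixtures module is first-class code: phantoms (Gaussian-profile bright
disks on a uniform background with Gaussian noise, 16-bit regime),
radial vignette gains (quadratic or Gaussian falloff hitting the corner
gain exactly), smooth random warp fields (coarse Gaussian control values,
bicubic upsampling, rescaled to a stated amplitude), mesh-grid target
images with 1-px antialiased edges and their exact corner lattices, and
whole on-disk acquisition trees. Default geometry mirrors the real
acquisition: 832 x 832 tiles, 11 x 14 grid, four channels, 732-px steps
(nominal 100-px overlap), 16-bit TIFF. A metadata-only mode writes the
metadata skeleton without pixels so whole-brain enumeration counts
(280 x 616 = 172,480 records) run in seconds.

Two conventions tie fixtures to the correction modules. Warping uses
inverse mapping: the warped image at `p` samples the source at `p - d(p)`,
clamped at edges — identical to the correction module's resampling — and
the reported true position of a feature is the exact fixed point
`p = q + d(p)`. The fixtures' Gaussian noise stands in for photon noise; it
is not Poisson, carries no fixed-pattern component, and phantom "cells"
have no processes or vasculature. Passing tests therefore demonstrate
correctness of the geometry and intensity pipeline, not segmentation-grade
realism.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: tiles of
128–832 px, grids of 2 x 2 to 3 x 3, sections of a few hundred pixels,
full-size (832/1564-px) images where the defaults themselves are under
test, and the metadata-only whole-brain tree for the counting checks. These
sizes keep the whole suite under half a minute while exercising every code
path at the paper-scale geometry at least once.

Other numerical decisions, in one place: NCC is computed by direct
per-placement sums (numerically safe; it matches a scalar double-loop
oracle to 1e-9 and better), zero-variance windows correlate at 0,
homography fitting normalizes coordinates before the SVD and rejects
collinear configurations, bicubic interpolation uses natural cubic splines
evaluated separably, all resampling is bilinear with edge clamping, and
16-bit output writing rounds half to even and counts clipped pixels in the
run manifest.

## Parallelism and reproducibility

Tiles are independent through normalization and correction; stitching needs
every tile of a (section, channel). The pipeline therefore parallelizes
over sections with a barrier per section, and the worker count is
contractually invisible in the output: single- and multi-worker runs
produce byte-identical section TIFFs, and repeated runs produce identical
checksums (both are asserted in the tests). Run manifests record the
configuration snapshot, per-section status including missing-tile and
clipped-pixel counts, timings and output checksums, and are written even
when individual sections fail.

## Known limitations

* One deformation model is shared by all channels; chromatic differences
  are not modeled (a per-channel model can be calibrated and applied by
  running the calibration per channel, but nothing automates it).
* No global mosaic optimization: translations are global constants, not
  per-tile refinements, which is the right model for a stage-scanned
  instrument but not for drifting stages.
* No inter-section registration; the block-face geometry is trusted.
* The Zarr writer covers exactly the layout it produces (v2, raw chunks);
  it is not a general Zarr client.
* NIfTI orientation metadata is a scaled identity; anatomical axes are not
  assigned.
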