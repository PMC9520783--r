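---
title: "Co-registering OPM-MEG sensor arrays with structural MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-registering OPM-MEG sensor arrays with structural MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmcoreg)
```

## The problem

Optically pumped magnetometers (OPMs) are cryogen-free magnetic sensors worn
on the scalp in a rigid, subject-specific helmet. Source localization of the
measured fields requires knowing each sensor's position and orientation
*relative to the subject's anatomy*, i.e. in the coordinate frame of the
structural MRI. Because the helmet is manufactured from a CAD design, sensor
slots, their radial orientations, and a set of reference markers are known
exactly in the helmet-design frame (the *device* frame). Co-registration is
then a chain of two rigid transforms:

* **Transform 1** (device → head): where the helmet sits on this subject's
  head, anchored to a *head* frame built from anatomical fiducials.
* **Transform 2** (head → MRI): where the subject's head sits in the MRI,
  found by matching digitized or scanned skin surface to the scalp surface
  segmented from the MRI.

Sensors are mapped by the composition; positions by the full transform,
orientation unit vectors by its rotation only. All coordinates are in
millimetres throughout.

The head frame follows the CTF-like convention: origin at the midpoint of the
left and right pre-auricular points, +X through the nasion, +Y towards the
left ear, +Z up. For optical scans, where the pre-auricular points may not be
visible, three picked face points in nasion/left/right order serve as
pseudo-fiducials; their exact placement is uncritical because the head frame
is only an intermediate — any consistent frame between the two transforms
yields the same composed device→MRI map.

## The three device workflows

**Electromagnetic stylus (`run_fastrak`).** The stylus digitizes the three
fiducials, free scalp points, and the helmet reference points. Transform 1 is
a labelled Kabsch alignment of the designed reference points onto their
digitized counterparts; its RMS residual is reported as the fiducial
registration error (FRE). Transform 2 registers the scalp points onto the MRI
scalp mesh by trimmed iterative closest point (ICP), optionally seeded from a
fiducial pre-alignment when MRI fiducials are supplied. Without that seed the
digitizer head frame and the MRI frame must already be roughly aligned, which
holds for typical MRI orientations; supplying MRI fiducials removes the
assumption, so the synthetic phantom always provides them.

**Structured-light scanner (`run_structured_light`).** The coloured scan
shows the subject wearing the helmet. Transform 1 finds the painted helmet
markers by HSV colour thresholding (default window H 0.2–0.66, S 0.3–1,
V 0.16–1, matched to green markers; hue on a 0–1 scale), clusters the
selected vertices into patches by single-linkage connected components
(linkage radius 10 mm, minimum patch size 5), and matches patch centroids to
the designed reference points by exhaustive permutation search — every
assignment is Kabsch-fitted and the minimum-FRE assignment wins. The search
is limited to 8 markers (8! ≈ 40k fits); a runner-up assignment within 2× of
the best FRE is rejected as ambiguous, which is exactly what happens for
symmetric layouts such as an equilateral triangle, so marker layouts should
be scalene. Transform 2 is a coarse match from at least four user-picked
landmark pairs followed by ICP of the cropped face region onto the MRI scalp.

**Laser scanner (`run_laser`).** The scan is colourless but geometrically
accurate, so Transform 1 registers the *designed helmet mesh* onto the
scanned helmet region (coarse four-pair match, then ICP); its RMS is reported
as the helmet match error. Transform 2 is identical to the structured-light
face stage.

**Depth correction (`apply_depth`).** In practice only a subset of slots is
used and each sensor is inserted to a measured depth. The insertion depth is
`depth = l − t − h` with `l` the sensor height, `t` the helmet thickness, and
`h` the exposed height measured with a caliper; flush insertion (`h = l − t`)
gives zero. Positions move by `depth` along the channel's radial orientation.
Stored orientations are taken to point inward (helmet → scalp), so positive
depth moves the sensor toward the scalp; `flip_direction = TRUE` flips the
convention for outward-pointing arrays. Orientations themselves never change,
and the correction commutes with rigid transforms, so it may be applied
before or after co-registration.

## Rigid alignment and ICP: numerical choices

`kabsch_align` is the SVD-based least-squares rigid fit with the determinant
correction, so a reflection is never returned — mirrored inputs yield a
proper rotation with a nonzero residual instead. No scaling is estimated:
helmet, head, and MRI are all metric. Degenerate geometry is detected when
the second singular value of the centred source falls below 1e-6 of the
largest (collinear or duplicated points).

`icp_register` is trimmed point-to-point ICP: each iteration finds, for every
transformed source point, the nearest *target vertex* (exhaustive compiled
search, ties to the lowest index for deterministic runs), discards the
`trim_fraction` worst pairs (default 0.1) and any pair beyond
`max_pair_distance` (unset by default), Kabsch-fits the retained pairs, and
accumulates the transform. Iteration stops when the retained-pair RMS changes
by less than `convergence_tol` (default 1e-4 mm) or after `max_iterations`
(default 100). The reported `rms` is the root-mean-square of retained
correspondence distances at the final iteration — the package's
operationalization of the "ICP fitting error" shown to users (mean or median
distance would be equally defensible; RMS is what the Kabsch step minimizes).
The retained-pair RMS is non-increasing across iterations, which the tests
assert per iteration. Correspondences always run source → target, with the
denser segmented surface as the target. Point-to-plane and globally
initialized ICP are out of scope; a coarse landmark-pair match (≥ 4 pairs, a
hard requirement) provides the initialization instead.

ICP quality bounds: face-surface fits above 2 mm RMS and helmet fits above
0.8 mm RMS indicate poor scan or digitization quality; `report()` warns at
exactly these thresholds.

## The synthetic phantom

`make_phantom` builds a deterministic, seeded stand-in for every input the
workflows need: a scalp as a triangulated ellipsoid (semi-axes 90 × 70 ×
100 mm — an adult-sized head) with a 12 mm Gaussian nose bump (the asymmetry
that makes face ICP well-posed and the head frame unambiguous), a helmet as
the 6 mm outward offset surface carrying 85 sensor slots with inward radial
orientations, 4 reference markers in a scalene layout as geodesic patches of
≈ 4 mm radius, and ground-truth device→head and head→MRI transforms drawn
from the seed (rotations ≤ 20°, translations ≤ 30 mm). Default mesh
resolution is a 64 × 108 parameter grid (≈ 6,900 scalp vertices, ≈ 4 mm
spacing; the face region holds ≈ 1,500 points), chosen as a realistic density
for segmented scalp surfaces while keeping a registration run in the
sub-second range. Modality noise defaults are 0.5 mm (stylus), 0.3 mm
(structured-light), 0.1 mm (laser), reflecting the devices' relative
accuracy.

Two deliberate design choices deserve emphasis:

* **Jittered sampling.** Vertex parameters are jittered uniformly within
  their grid cell. A strictly regular parameter lattice gives point-to-point
  ICP spurious lattice-shift minima (rotations near one grid period alias);
  real scans are not lattice-sampled, and the jitter removes the artifact.
* **Vertex-exact correspondence.** Simulated digitizations and scans sample
  the phantom's mesh vertices (plus deterministic marker-patch points), so at
  zero noise every measured point has an exact counterpart on the reference
  surface and the pipelines recover ground truth to machine precision. The
  designed reference points are *defined* as the device-frame centroids of
  the marker-patch point sets, making marker detection exact at zero noise as
  well. Real scans resample the surface continuously, so real registrations
  carry an additional surface-sampling error that the noiseless phantom does
  not probe; the noisy phantom conditions (where points are displaced off the
  surface) are the more realistic benchmark. Passing the noiseless tests
  therefore validates the *geometry chain* (frames, transforms, composition,
  correspondence logic), not scanner physics; the phantom also does not model
  holes, specular dropout, or other scanner artifacts.

`simulate_scan` returns, alongside the cloud, the scriptable equivalents of
the GUI interactions the workflows need: the three face picks, face/helmet
region index selections, and the coarse landmark pairs (source side as
realized — noisy — scan coordinates, target side exact in the destination
frame). At the command line, `select_by_sphere` replaces interactive region
picking.

## What the accuracy checks compute

The test suite and `scripts/acceptance.R` recompute, from scratch at run
time, under the default phantom conditions (20 seeded trials, one phantom
per base seed):

* mean face-ICP RMS with 0.5 mm scan noise after an initialization within
  5 mm / 5° of the true pose — compared against the 2 mm face quality bound;
* mean designed-helmet-to-scan ICP RMS with 0.1 mm scan noise after a
  coarse four-pair match — compared against the 0.8 mm helmet quality bound;
* exact noiseless recovery for all three pipelines, Kabsch recovery over
  1000 random motions, ICP monotonicity/oracle/equivariance properties, the
  depth formula, and the marker-extraction chain.

These are desk-scale synthetic analogues: physical phantom accuracies
(sub-millimetre for a laser scanner, a couple of millimetres for a
structured-light scanner) depend on hardware and cannot be reproduced in
software, which is why the package reports registration *fit* errors and
property-based checks instead.

## Known limitations

* Rigid transforms only: flexible caps (where the sensor array deforms per
  subject) are unsupported, as are similarity or non-rigid fits.
* Point-to-point ICP needs a fair initialization (fiducials or ≥ 4 coarse
  pairs); there is no global registration fallback.
* Marker matching is exhaustive and limited to 8 markers, and refuses
  symmetric layouts by design.
* MRI scalp segmentation is upstream: the package consumes a scalp mesh
  (PLY), it does not produce one. PLY support covers ASCII and
  binary-little-endian dialects with triangular faces.
* HSV windows must not wrap hue 0/1; wrapping colours (red markers) need two
  windows and a combined selection.
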