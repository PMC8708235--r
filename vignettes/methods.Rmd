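---
title: "From rotating-arm depth scans to true-scale skin images: the methods behind dermascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rotating-arm depth scans to true-scale skin images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-body photographic screening for melanoma needs to answer a metric
question from ordinary photographs: how large is this nevus, and are its
proportions changing? A camera mounted on a rotating arm sees every patch
of skin at some distance and under some obliquity, so apparent size falls
with distance and apparent shape is compressed by the cosine of the
surface tilt. Neither effect can be undone from the photograph alone.
`dermascan` implements the geometric machinery that undoes both: it builds
a triangle-mesh model of the body from the arm's depth scanners, links
every photograph to the mesh, and locally resamples the photograph onto
the surface tangent plane -- an orthorectified patch with a known scale in
pixels per millimeter, on which diameters, areas and axis ratios are
measured in physical units.

## Coordinate systems and the projection chain

Four frames are used. Each depth scan arrives in its scanner's own frame
(DCS). A device parked at arm angle $\alpha$, height $h$ and arm radius
$r$ maps scanner points to the object frame (OCS; origin on the floor, Y
up the rotation axis) by a translation $[0, h, -r]^T$ followed by the
Y-rotation $R_y(\alpha)$. This ordering is what makes a point on the
rotation axis independent of $\alpha$ -- the defining property of the
rig. The camera transform is the inverse motion with two calibration
terms, a matrix $Q$ and an offset $T$, absorbing mounting imperfections:

$$p_{CCS} = Q\,\bigl(R_y(-\alpha)\,p_{OCS} - [0, h_C, -r_C]^T\bigr) + T.$$

An ideal pinhole maps camera points to pixels,
$[x_t, y_t]^T = p_{xy}/(d\,z) + c$, with a single constant $d$ and the
principal point $c$ (defaulting to the image center; the pure projection
formula has no pixel origin, real images do). Lens distortion is out of
scope; the virtual cameras of the synthetic data are exactly pinhole.

For rectification a virtual orthographic camera is erected at a chosen
surface point $V$: its optical axis is antiparallel to the unit surface
normal, its X axis is horizontal (parallel to the OCS XZ plane), and its
Y axis completes the right-handed orthonormal rotation $G$. When the
normal is within numerical tolerance of vertical, every horizontal
direction is equally valid and the frame falls back to $X = (1,0,0)$
deterministically. Orthographic projection is simply
$[x_g, y_g]^T = s\,[x_{VCS}, y_{VCS}]^T$ with a free scale $s$ (the
interface takes pixels per millimeter and converts; OCS is metric). Since
$G^{-1} = G^T$, back-projection from patch coordinates to the tangent
plane is closed-form, and the resampling chain

tangent plane $\to$ OCS $\to$ CCS $\to$ source pixel

is evaluated for every output pixel, with bilinear interpolation of the
source (bicubic behind a flag). For a planar surface this chain is an
exact plane-to-image homography; the test suite checks agreement with an
independently fitted homography below half a pixel. On curved anatomy the
tangent plane is a local approximation whose error grows with patch size,
so the default patch is capped at 40 x 40 mm -- per-lesion patches, not
unfolded charts.

## Building the body model

The pipeline follows the classical depth-scan chain, with every stage a
separate, testable function:

1. **Crop** to the known subject box (closed box: boundary points kept).
2. **Voxel downsample**: points bucketed by `floor(p / voxel)` on a grid
   anchored at the origin, each voxel replaced by the member mean
   (default 1 cm; 5 mm in the fidelity studies).
3. **Ring registration.** All devices at one arm stop move rigidly with
   the arm, so scans are grouped per stop and the 8 stops form a closed
   ring. Consecutive stops are registered by point-to-point ICP
   (closed-form SVD fit per iteration, correspondence cap 2 cm by
   default, iteration cap 50, relative-residual tolerance 1e-6). Two
   correspondence guards matter on partially overlapping views: a
   mutual-nearest-neighbor refinement stage, which removes the drag
   exerted by regions only one view covers, and an optional
   normal-compatibility gate (reject pairs whose normals disagree by more
   than 60 degrees), which stops wrong-side matches across thin
   structures such as arms. The remaining per-edge bias is a
   discretization effect that scales with the scan point spacing -- hence
   the registration studies use dense scans -- and is further reduced by
   iterating the whole ring coarse-to-fine (caps 2 cm, 8 mm, 5 mm),
   re-registering after each loop closure.
4. **Loop closure.** The ring of pairwise transforms rarely composes to
   the identity. A pose graph over per-stop corrections (stop 1 fixed)
   minimizes the squared SE(3) log of each edge residual by
   Levenberg-Marquardt on a rotation-vector + translation
   parameterization; the corrected edges compose to the identity exactly
   by construction. No algorithm is prescribed for this step by the
   acquisition protocol; this is the package's choice.
5. **Outlier removal**: a point is dropped when its mean distance to its
   k nearest neighbors (k = 20) exceeds the cloud mean by more than one
   standard deviation of those distances -- the threshold that removes
   loose points without eroding cloud edges. The filter is not
   idempotent; a second pass may remove more.
6. **MLS smoothing**: each point is projected onto a weighted
   least-squares polynomial (degree 2) fitted to its 5 cm neighborhood in
   the neighborhood's PCA frame. 5 cm smooths double-wall registration
   artifacts and sensor waviness while preserving body geometry; points
   on an exact plane are reproduced, isolated points pass through.
7. **Normals**: smallest-eigenvalue eigenvector of the k-NN covariance
   (k = 30), oriented toward each point's acquiring scanner -- per-point
   viewpoints survive merging.
8. **Surface reconstruction.** The oriented cloud is turned into a
   watertight mesh by sampling an implicit signed-distance field -- the
   Gaussian-weighted average of signed distances to the tangent planes of
   the k = 10 nearest oriented points -- on a regular lattice, and
   extracting the zero level set by marching tetrahedra (Kuhn
   subdivision, vertex welding on lattice edges, triangle orientation
   toward positive field). The lattice follows the octree-depth
   convention: depth $D$ gives $2^D$ cells along the longest axis
   (default $D = 7$, about 1.5 cm on an adult body), so depth trades
   smoothness against detail. The outermost lattice layer is clamped
   positive so the level set always closes inside the grid, and minor
   disconnected shells are dropped, keeping the largest component. The
   output is checked watertight (every edge shared by exactly two
   triangles, once per direction).

## Linking photographs to the mesh

Visibility and picking use a deterministic software rasterizer rather
than any screen machinery. Two aligned buffers are rendered per view: a
*triangle-index mosaic* (each triangle a unique 24-bit id, background 0)
and a *barycentric shading* buffer holding the perspective-correct
barycentric weights of each pixel center in its winning triangle. A pixel
belongs to a triangle when its center lies inside or on the boundary of
the projection; depth ties break to the lower triangle id, which
deterministically resolves shared edges (a boundary-inclusive variant of
the usual top-left convention). Back faces are culled; the z-buffer keeps
the nearest surface. Index buffers export as 8-bit RGB PNG; barycentric
buffers as 16-bit PNG, because 8-bit weight quantization (~0.4%) would
dominate the picking error budget, while 16 bits keep it below 1e-4.

A triangle receives its texture from the view where its projected area is
largest -- the view that pictures that skin patch at the highest
resolution -- but only among views where it passes the visibility test:
the mosaic must show the triangle's own id at its projected centroid and
three edge midpoints (all four; triangles covering no pixel center fail).
Area ties break to the lowest view id. Picking inverts the pipeline: the
index buffer names the triangle under a pixel, the barycentric buffer
gives the weights, and the weighted vertex combination returns the 3D
surface point, which reprojects to the picked pixel within half a pixel.

## The synthetic scan sessions

No volunteer scans ship with the package; all validation runs on
synthetic sessions whose ground truth is analytic. The phantom torso is a
generalized cylinder -- an elliptic cross-section (default semi-axes
15 x 11 cm) with a low-order azimuthal lobe modulation and, for
registration studies, a pronounced Gaussian waist -- capped by
half-ellipsoids, optionally flanked by arm cylinders. The shape features
are not decoration: a surface of revolution leaves the azimuth
unobservable to registration, a straight cylinder leaves the vertical
slide nearly free, and arms both anchor the azimuth and create the
occlusions the visibility test must handle. The registration phantom
(`body_phantom_spec()`) therefore carries waist + lobes + arms, the way a
real body carries shape cues in every direction.

Markers live on the cylindrical part only, where the surface is
developable: the unrolled chart (arc length, height) is an isometry, so a
"printed" 2 cm disk defined by chart distance is an exact geodesic disk.
Markers are painted by the analytic texture function, not by raster
textures, so no resampling error enters the ground truth; tag corners,
marker centers and normals are carried in closed form. Virtual
photographs render this texture through the full projection chain;
virtual depth scans raycast the same mesh and add Gaussian depth noise
along the ray (default sigma 2 mm), optional dropout and clutter. Camera
intrinsics default to a 2 cm marker spanning ~100 px at 0.8 m; scanner
resolutions are chosen per study (registration accuracy scales with scan
density). Arm-mounting errors are emulated by rigid per-scan
perturbations whose exact values are recorded for recovery tests.

What the phantom does *not* emulate: skin texture and specularity,
subject motion during the sweep, sensor-specific noise structure, or lens
distortion. Passing tests therefore demonstrate the geometric correctness
of the pipeline under the stated acquisition model, not robustness to
every clinical nuisance.

## The marker study and its expected values

The rectification study prints twelve 2 cm markers at tilts 0-60 degrees
relative to their source camera (azimuth steps on three height rows,
cameras offset from the rows so distances vary). In the source images the
fitted ellipse ratio grows to ~2 at 60 degrees and the apparent area
falls accordingly; in the orthorectified patches the mean ratio returns
to within a few percent of 1 and the area to within a few percent of
$\pi$ cm$^2$ -- the geometric truth for a disk of radius 1 cm. (A circle
of 2 cm *diameter* has area $\pi$ cm$^2$, not $2\pi$; the implementation
uses $\pi r^2$ throughout.) Ellipses are fitted by second central moments
(exact for filled ellipses, no iterative failure modes); the marker disk
is segmented by Otsu's threshold plus center-connected component
labelling with hole filling; tag shear angles use the generator's
ground-truth corners transferred analytically, so no corner detector
enters the measurement. Scale for the original-image area uses the pixel
footprint at the marker's depth, $d\,z$ mm/px.

## Numerical choices and degenerate inputs

* Angles are degrees at every config/CLI boundary, radians internally;
  OCS is in meters; patch scale is pixels per millimeter at the
  interface.
* Image coordinates are 0-based with the origin at the top-left pixel
  center, x right, y down. Patch centers sit at `(size - 1) / 2`, the
  exact center pixel for odd sizes.
* The unit triangle normal renormalizes the cross product (the
  `|B-A||C-A|` denominator of the raw formula is a unit normalizer only
  for right-angle corners); degenerate triangles raise an error.
* ICP requires at least 3 correspondences within the cap and reports a
  hard error otherwise (disjoint clouds); exact-tie voxel bucketing goes
  to the lower-index voxel via `floor`.
* Sub-pixel triangles are declared invisible per view rather than
  guessed.
* The registration-recovery comparison is gauge-free (per-edge relative
  poses): a ring of pairwise registrations determines absolute poses only
  up to one global rigid motion, so comparing edges against the injected
  relative perturbations is the well-posed metric; the loop composition
  is checked against the identity separately. Mesh-to-truth RMS after a
  perturbed run removes the same gauge by rigidly aligning first.

## Problem sizes used by the validation studies

The studies fix moderate sizes that a laptop handles in minutes: the
marker study renders three 1440 x 960 views of a ~27k-triangle phantom;
the registration study uses eight 768 x 576 depth scans (~66k points
each, 2.6 mm spacing at 1 m) with three coarse-to-fine ring rounds; the
fidelity study uses eight 480 x 360 scans with 2 mm noise, 5 mm voxels
and lattice depth 7. Scan density is the accuracy lever for point-to-point
ICP: halving the spacing roughly quarters the residual per-edge bias in
our measurements.

## Known limitations

* Point-to-point ICP on smooth, feature-poor geometry has flat cost
  directions; the synthetic phantom deliberately carries shape features,
  and real bodies do too, but a subject standing perfectly cylindrical
  (arms fully occluded, loose garment) would degrade azimuthal recovery.
* The tangent-plane patch ignores curvature inside the patch; for a 4 cm
  patch on a 15 cm-radius torso the edge error is a few tenths of a
  millimeter, but it grows quadratically with patch size.
* Subject motion between stops is not modeled or compensated (rigid
  per-stop poses only).
* The index/barycentric buffers identify surfaces; they are not
  visualization renders (no lighting, no anti-aliasing), and anti-aliasing
  would actually corrupt id decoding at silhouettes.
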