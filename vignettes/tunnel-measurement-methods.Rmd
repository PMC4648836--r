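---
title: "Measuring drilled bone tunnels from CT: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring drilled bone tunnels from CT: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunnelmetry)
```

## The problem

After anterior cruciate ligament (ACL) reconstruction, the drilled femoral
tunnel tends to widen over time. When a revision is planned, the surgeon
needs the current tunnel diameter and position; the diameter immediately
after surgery is, to a good approximation, the diameter of the drill used,
which makes the drill record a natural ground truth for evaluating
measurement methods on immediate post-operative CT.

`tunnelmetry` implements four ways of measuring a tunnel's diameter — three
that operate on a 3D surface model of the tunnel wall reconstructed from the
CT, and the clinical 2D method that measures directly on the image planes —
together with the agreement statistics used to compare methods against the
drill size, and a synthetic phantom generator so that the whole chain can be
validated against known diameters without patient data.

## From volume to tunnel model

1. **Threshold segmentation** (`threshold_segment`): bone is labelled by a
   density range `[low, high]`, mirroring the clinical density-range
   segmentation. No morphology is applied at this stage.
2. **Cavity extraction** (`extract_tunnel_cavity`): the tunnel is the empty
   space inside bone. Morphologically closing the bone mask with a
   Euclidean ball whose radius exceeds the tunnel radius (default 6 mm,
   comfortably above the largest 4.5 mm drill radius) fills the tunnel;
   subtracting the bone mask and keeping the 26-connected component around
   a user-supplied seed point isolates the cavity. The ball is defined in
   millimetres and realised through an exact anisotropic distance
   transform, so the anisotropic CT spacing (about 0.98 x 0.98 x 0.75 mm)
   does not bias the morphology. One numerical detail: the erosion step
   uses the closing radius plus half a voxel diagonal. On a discrete grid
   the dilation reaches up to half a voxel beyond the r-offset surface, and
   eroding by exactly r would leave a spurious one-voxel film of "cavity"
   over the entire bone surface, connected to the tunnel through its
   apertures; the overshoot suppresses it while leaving the tunnel interior
   untouched. The closing is computed on a zero-padded grid so image
   boundaries never truncate the ball.
3. **Iso-surfacing** (`mask_to_mesh`): the cavity mask is surfaced at level
   0.5 by marching tetrahedra on the Kuhn 6-tetrahedron cube decomposition,
   which is crack-free across cube faces, with vertices interpolated along
   grid edges. By default the 0/1 field is first smoothed with a 1-voxel
   Gaussian so vertices land at sub-voxel positions; surfacing the raw mask
   is available via `smooth_sigma_voxels = 0`. Face normals are oriented
   into the lumen. For measurement, the rounded end caps that closing
   leaves at the apertures are removed with `trim_tunnel_ends` (default:
   15% of the axial extent at each end), which restores the open tube a
   drilled tunnel actually is.

Coordinate convention throughout: 1-based voxel indices in (x, y, z) order;
world mm = origin + (index - 1) * spacing. Readers and writers (NIfTI via
RNifti, a minimal NRRD implementation, STL/PLY for meshes) honour this
convention and are round-trip tested.

The clinical workflow this emulates included a manual revision step after
segmentation; this package replaces it with the deterministic morphology
above, deliberately, so results are reproducible bit for bit.

## The four measurement methods

**Best-fit cylinder** (`fit_cylinder`). An analytic cylinder is fitted to
the entire tunnel wall by minimising the sum of squared orthogonal distances
of the mesh vertices to the cylinder surface; the residual of a point $p$
for a cylinder (axis point $c$, unit direction $d$, radius $r$) is
$\lVert (p-c) - ((p-c)\cdot d)\,d \rVert - r$. The axis is initialised from
the first principal component and refined over a two-parameter tangent
perturbation; for each candidate direction the optimal centre and radius
come from a circle fit in the projected plane (Kåsa algebraic fit, then
Gauss–Newton on the geometric objective to a 1e-10 gradient tolerance).
Diameter = $2r$. Point clouds without a dominant axis (principal extent
ratio below 1.2) are rejected as degenerate.

**Transverse section** (`transverse_section_diameter`). A centerline is
extracted by slab-binning the vertices along the principal axis (20 slabs by
default, slabs with fewer than 10 vertices dropped) and taking slab
centroids; a plane is placed at an arc-length fraction of that centerline
(default 0.5, "mid-length") perpendicular to the local tangent; the
mesh–plane intersection is chained into loops; the loop containing the
centerline point (innermost if nested, with a warning) is circle-fitted as
above. A plane that crosses an aperture yields an open chain and an explicit
error suggesting a different station.

**Wall thickness** (`wall_thickness`). From every triangle centroid a ray is
cast along the triangle's into-lumen normal; the distance to the first
triangle hit — ignoring triangles whose centroid lies within an exclusion
radius (default 1 mm, larger than a typical triangle edge) of the origin —
is that triangle's thickness. Rays that escape through an aperture are
misses, reported as a fraction and excluded from the summary. The summary
diameter is the unweighted mean over triangles (area-weighted by flag). On a
rough surface the normals deviate from the true diameter direction and the
rays traverse chords, which are never longer than the diameter; the method
therefore systematically underestimates on realistic segmentations, and the
package's validation asserts exactly that directional failure rather than
pretending the method works.

**2D CT method** (`ct2d_diameter`). In each canonical plane (axial, coronal,
sagittal) through the tunnel mid-point, the in-slice connected component of
the tunnel mask is contoured at the 0.5 level (sub-pixel, on a lightly
smoothed copy of the slice) and its minimum Feret width — the narrowest
pair of parallel supporting lines — is taken as that plane's measurement;
the method diameter is the mean of the three planes, as in the clinical
protocol. The *minimum* width is used because an oblique cut of a cylinder
is an ellipse (or strip) whose minor width equals the true diameter;
a maximum-chord variant is available for sensitivity analysis. This choice
resolves an ambiguity the clinical protocol leaves open (which line the
operator draws across an oblique section); real operators may behave
somewhere between the two variants.

## Agreement statistics

`icc_2_1` implements the two-way random-effects, single-measures,
absolute-agreement intraclass correlation from the ANOVA mean squares:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

with the F-based 95% confidence interval of the McGraw–Wong ICC(A,1)
construction (Satterthwaite degrees of freedom for the rater term) — the
construction implemented by the major statistics packages for this form.
Negative estimates are reported as-is. The qualitative bands are the
conventional ones: above 0.75 excellent, 0.40–0.75 (both boundaries
inclusive) fair to good, below 0.40 poor. An all-equal table is defined as
perfect agreement (ICC 1, degenerate interval) with a warning rather than a
0/0 failure. The drill size enters as a rater column in a two-column
subjects x raters table, which is how "agreement with the drill size" is
framed. `agreement_report` assembles the per-method table (ICC, CI,
classification, mean ± SD signed difference) and, when repeat measurements
are supplied, a per-method intra-rater table.

The implementation is checked two ways: against a definitional
sums-of-squares oracle on random tables (to 1e-10), and against frozen
reference values from an independent implementation on the classic
Shrout–Fleiss ratings.

## The phantom generator: what it emulates and what it does not

`make_phantom_volume` voxelizes a three-level block — background 0,
cancellous interior 300, cortical shell 1200 (HU-like; the clinical protocol
specifies kV/mAs, not calibrated HU, and any separable three-level phantom
suffices for threshold segmentation) — pierced by a cylindrical tunnel,
then applies isotropic Gaussian blur (sigma 0.6 voxels, modelling partial
volume) and additive Gaussian noise (SD 20 density units). Defaults mirror
the clinical protocol where it is stated: in-plane spacing 500/512 mm,
slice increment 0.75 mm, drill diameters on the 0.5 mm ruler grid from 5.0
to 9.0 mm, 24 tunnels per cohort. Where the protocol is silent the package
chooses once: tunnel length 30 mm (a typical femoral socket is 25–35 mm),
bone block 46 x 46 x 22 mm, cortical shell 1.5 mm, and axis obliquity
20–40 degrees from the slice normal (uniform), reflecting the oblique
femoral tunnels of anatomic reconstruction. With that geometry the tunnel
pierces both block faces, so the cavity has open apertures like a drilled
socket, and the generator validates that the tunnel stays laterally inside
the volume. Every random draw flows through an explicit seed; cohort
phantoms get per-tunnel seeds derived from the master seed.

What the phantom does **not** emulate: knee anatomy (condyles, trabecular
texture), scanner physics (beam hardening, the metal artifact of the
cortical fixation button), asymmetric tunnel enlargement, and the manual
segmentation editing of the clinical workflow. Passing the validation
therefore demonstrates that the measurement chain is correct and unbiased on
cylindrical cavities under CT-like sampling, blur and noise — not that it
is robust to everything a real post-operative knee can present.

## Validation design and problem sizes

The patient images behind the original study are not public, so the
package's acceptance checks are property-based, at sizes chosen to run
comfortably on a laptop:

- *Exact geometry*: on analytic cylinder meshes (r = 2.5, 3.25, 4.5 mm,
  arbitrary orientation, 256 circumferential x 25 axial vertices) the
  cylinder fit and transverse section recover 2r within 1e-3 mm and the
  mean wall thickness within 1%.
- *Voxel scale*: a 24-tunnel cohort at the clinical spacing with default
  blur and noise; transverse-section, cylinder-fit and 2D methods must each
  reach a mean absolute error of at most 0.5 mm and ICC(2,1) vs the drill
  size of at least 0.85.
- *Failure direction*: on vertex-noise-perturbed cylinders (SD 0.15 mm,
  10 seeds) the mean wall thickness must not exceed the cylinder-fit
  diameter in at least 9 of 10 seeds, and on the noisy cohort the
  transverse-section ICC must be at least the wall-thickness ICC — the
  qualitative ordering the clinical comparison found.
- *Statistics*: the ICC matches the definitional ANOVA oracle to 1e-10 on
  100 random tables.
- *Determinism*: a simulated study repeated with the same seed produces
  bit-identical CSV outputs.

## Numerical choices and known limitations

- Circle fits: Kåsa initialisation + geometric Gauss–Newton (tolerance
  1e-10, max 100 iterations); cylinder fit: BFGS over the axis tangent
  parameters (relative tolerance 1e-14, max 200 iterations). These are
  stated so results are bit-reproducible given a mesh.
- Tie-breaks: among multiple section loops, the loop containing the
  centerline point wins; nested loops resolve to the innermost (smallest
  area). Vertices exactly on the section plane are nudged by 1e-12 mm.
- The 1-voxel iso-surface smoothing trades a small inward curvature bias
  (about sigma^2 / 2R, i.e. roughly 0.1–0.3 mm on the diameter at clinical
  spacing) for much lower vertex noise; the bias is visible in the cohort
  validation as a small negative mean difference of the 3D methods and is
  well inside the 0.5 mm acceptance band. Surfacing the raw mask removes
  the bias at the cost of lattice-quantised vertices.
- The wall-thickness exclusion radius (1 mm) must exceed the local triangle
  size; extremely coarse meshes would need a larger value.
- `fit_centerline` assumes a mostly straight, tube-like cavity. Slabs cut
  the tube obliquely where it ends or bends, so the outermost centerline
  points and points at a bend carry a sideways bias of order r times the
  bend angle (about 7% of the radius on a 10-degree miter-jointed test
  tube, versus well under 1% in the straight interior). The measurement
  pipeline trims the tunnel ends and measures at interior stations, where
  the recipe is unbiased; strongly curved or branching cavities are out of
  scope.
- Density thresholds for real scans are scanner- and protocol-dependent and
  must be supplied by the user; the defaults are calibrated to the phantom
  levels only.
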