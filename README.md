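# tunnelmetry

Measuring drilled bone tunnels — such as the femoral tunnels of anterior
cruciate ligament (ACL) reconstruction — from computed tomography. After an
ACL reconstruction the tunnel diameter immediately post-op equals the drill
diameter, which makes the surgical drill record a ground truth for judging
measurement methods. `tunnelmetry` implements the four methods a revision
surgeon might use and the statistics to compare them:

- **Best-fit cylinder**: an analytic cylinder fitted to the whole tunnel
  wall by orthogonal-distance least squares; the residual of point *p* for
  a cylinder (centre *c*, unit axis *d*, radius *r*) is
  ‖(p−c) − ((p−c)·d)d‖ − r, and the diameter is 2r.
- **Transverse section**: a centerline is fitted through the tunnel lumen
  and a circle is fitted (Kåsa + geometric refinement) to the tunnel wall
  in the plane perpendicular to the centerline at its mid-length.
- **Wall thickness**: from each triangle of the tunnel-wall mesh, a ray
  along its into-lumen normal to the opposite wall; the mean recorded
  distance. Included because it is offered by clinical 3D software — and
  the package's validation shows *why* it fails (rays traverse chords, so
  rough surfaces are systematically under-measured).
- **2D CT**: the clinical method — the mean of the tunnel widths measured
  in the axial, coronal and sagittal planes through the tunnel mid-point
  (sub-pixel contours, minimum Feret width).

Method agreement with the drill size is quantified by the two-way random,
single-measures, absolute-agreement intraclass correlation ICC(2,1) with an
F-based 95% CI, classified as excellent (> 0.75), fair to good (0.40–0.75)
or poor (< 0.40), plus mean ± SD signed differences.

Because no patient CTs ship with the package, it includes a synthetic CT
phantom generator: a two-density bone block (cancellous core, cortical
shell) pierced by a cylindrical tunnel of known drill diameter, voxelized
at CT-like anisotropic spacing with partial-volume blur and noise. The
whole pipeline — segmentation by density range, morphological cavity
extraction, marching-tetrahedra iso-surfacing, all four measurements,
agreement report — is validated by parameter recovery on such phantoms.

## Worked example

Simulate a phantom with a 7 mm drill, tilted 30° from the scan axis, and
measure it all four ways:

```r
library(tunnelmetry)

spec <- phantom_spec(drill_diameter_mm = 7,
                     tunnel_axis = c(sin(pi/6), 0, cos(pi/6)),
                     seed = 11)
ph  <- make_phantom_volume(spec)
res <- measure_volume_tunnel(ph$volume, seed_point_mm = c(0, 0, 0),
                             config = run_config(),
                             truth = ph$truth, id = "demo")
res$records[, c("method", "diameter_mm", "error_mm")]
#>               method diameter_mm     error_mm
#> 1       cylinder_fit    6.735594 -0.264406100
#> 2 transverse_section    6.729931 -0.270069360
#> 3     wall_thickness    6.713698 -0.286301949
#> 4               ct2d    6.994931 -0.005069061
```

All three 3D methods recover the 7 mm drill to within ~0.3 mm (the small
negative offset is the documented iso-surface smoothing bias); the 2D
method lands within 0.01 mm here because the mid-point section of a clean
cylinder is exactly what it measures.

A full simulated study — 24 phantoms with drill diameters drawn from the
5.0–9.0 mm ruler grid in 0.5 mm steps and random 20–40° obliquity —
produces the per-method agreement table:

```r
study <- run_simulated_study(run_config(n_tunnels = 24, seed = 1))
study$report$agreement
#>               method  n       icc     ci_low   ci_high classification mean_diff_mm sd_diff_mm
#> 1       cylinder_fit 24 0.9731332 0.03642847 0.9951143      excellent  -0.32393285 0.05445433
#> 2 transverse_section 24 0.9766569 0.16513466 0.9952461      excellent  -0.28526008 0.12523462
#> 3     wall_thickness 24 0.9707102 0.03735806 0.9945389      excellent  -0.33769265 0.08171437
#> 4               ct2d 24 0.9925515 0.97387021 0.9972461      excellent  -0.09345003 0.14784385
```

On these clean cylindrical phantoms every method classifies as excellent;
the ranking (transverse section above wall thickness, which carries the
largest bias) and the direction of the wall-thickness error match what is
seen clinically, where real segmentation roughness degrades wall thickness
far more severely. `wall_thickness` is the mean over triangles; rays that
escape through the tunnel apertures are counted as misses and reported.

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/cli/tunnelmetry.R simulate --n 24 --seed 1 --out study_out
Rscript inst/cli/tunnelmetry.R measure --in vol.nii.gz --seed-mm 0,0,0 \
    --drill drill.csv --out meas_out
```

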