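# monoloc

3D localization of interventional devices from a **single monoplane X-ray
projection**, using a co-registered vascular centerline model.

## The problem

Fluoroscopy guides most catheter-based cardiovascular procedures, but a
single projection has no depth: a 2D image point constrains the device
only to a back-projection ray. Biplane systems, rotational acquisitions
and electromagnetic tracking all restore depth at the cost of dose,
time, or extra hardware. When the device is known to travel **inside a
vessel**, a patient-specific 3D centerline model (extracted from
pre-procedural CT and registered to the X-ray system) supplies the
missing constraint: the device must lie on the vessel tree, so depth can
be read off the centerline.

`monoloc` is for researchers in image-guided interventions who want a
compact, fully testable reference implementation of this idea —
including the C-arm camera model, fiducial registration, the epipolar
reference reconstruction used for validation, template tracking, and a
synthetic phantom generator to exercise all of it.

## The method

Let `s` be the X-ray source position, `p_2D` the picked 2D device
position, and `p'_2D` its position on the physical detector plane in 3D
system coordinates. Every candidate centerline point `c ∈ C` defines a
projection ray `c − s`; the localized 3D position is the candidate whose
ray is most parallel to the working point's ray:

```
p_3D = argmin_{c ∈ C} ‖ (c − s) × (p'_2D − s) ‖²
```

Because `‖(c − s) × w‖ = ‖w‖ · dist(c, ray)` for the fixed vector
`w = p'_2D − s`, this argmin coincides with the candidate closest to the
back-projection ray — an equivalence the test suite asserts against a
brute-force perpendicular-distance oracle on randomized scenes.

Two practical safeguards surround the argmin:

* **Ambiguity flag** — when vessels superimpose in projection, the best
  point on another branch can come within a relative tolerance (default
  1 %) of the minimum; the result is flagged rather than silently
  trusted.
* **Continuity restriction** — for point sequences (a device advancing
  across frames), each localization after the first is restricted to
  the *geodesic* neighborhood (default 10 mm along the tree) of the
  previous result. Branches that overlap in the image but are far away
  along the vessel tree are thereby excluded, which repairs the
  wrong-branch failures of unconstrained single-view localization.

Supporting components: a C-arm pinhole model parameterized by LAO/RAO
and CRAN/CAUD angulation, SOD and SID; orthogonal-Procrustes
(rigid/similarity) and affine fiducial registration; two-view epipolar
triangulation (midpoint of the common perpendicular) as the reference
reconstruction; zero-mean normalized cross-correlation template
tracking with optional appearance-model (matched-filter) templates and
sub-pixel refinement; 3D-ED and iso-center-plane 2D-ED error metrics
with mean/std/median/max summaries.

## Worked example

Localize five radio-opaque markers placed in the carotid branch of the
synthetic aortic-arch phantom, with the markers displaced 1.5 mm off
the vessel centerline (a guidewire hugging the wall) and integer-pixel
picks, viewed at LAO 30°:

```r
library(monoloc)

ph   <- make_phantom(phantom_spec(marker_radial_offset_mm = 1.5, seed = 7))
g    <- pose_to_geometry(carm_pose(30, 0))          # LAO 30, SOD 750 / SID 1000
tree <- resample_centerline(ph$tree, 0.5)           # 0.5 mm sampling
px   <- project_markers(g, ph$markers_mm, quantize = TRUE)

res <- localize_sequence(g, px, tree, window_mm = 15)
summarize_errors(ed3d(as.matrix(res[, c("x", "y", "z")]), ph$markers_mm))
#> m = 1.57 mm, std = 0.06 mm, mdn = 1.55 mm, max = 1.66 mm (n = 5)
branch_accuracy(res, ph$truth$branch_id)
#> [1] 1
```

All five markers land on the correct branch and the 3D error is the
marker's own 1.5 mm off-center displacement plus a fraction of the
0.5 mm sampling and pixel quantization — the intrinsic accuracy floor
of centerline-based localization is the distance of the device from the
centerline, bounded by the vessel radius.

A single point works the same way:

```r
localize(g, px[1, ], tree)
#> 3D localization: branch 'carotid' index 27 at (1.40, -12.19, 45.48) mm
#>   perp. ray distance 0.6907 mm over 382 candidates
```

The same operations are available from the shell via the thin wrapper
`inst/cli/monoloc` (subcommands `simulate`, `localize`, `triangulate`,
`register`, `track`, `evaluate`, `run`).

## Scope

The package consumes pre-extracted centerlines (CSV/JSON/VTK polyline
formats); centerline extraction from CT, intensity-based 2D–3D
registration, motion compensation, and learned device detectors are out
of scope. See the vignette in `vignettes/` for the model assumptions,
parameter choices and limitations.
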