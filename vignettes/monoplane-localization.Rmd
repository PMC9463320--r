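---
title: "Monoplane 3D device localization on vascular centerline models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monoplane 3D device localization on vascular centerline models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoloc)
```

## The model and its assumptions

A monoplane fluoroscopy image constrains a device position to the
back-projection ray through the X-ray source. `monoloc` resolves the
remaining depth ambiguity with a single anatomical prior: *the device
travels inside a vessel whose 3D centerline is known and registered to
the X-ray system*. The localized position is the centerline point whose
projection ray is most parallel to the working point's ray,

$$p_{3D} = \arg\min_{c \in C} \left\| (c - s) \times (p'_{2D} - s) \right\|_2^2,$$

with $s$ the source and $p'_{2D}$ the picked pixel embedded on the
physical detector plane. Since
$\|(c-s)\times w\| = \|w\|\,\mathrm{dist}(c,\mathrm{ray})$ for the fixed
vector $w = p'_{2D}-s$, the argmin is exactly the candidate nearest the
ray in the perpendicular sense. The implementation keeps the raw
cross-product objective; the equivalence to the normalized point-to-ray
distance is asserted in the test suite against an independently coded
oracle rather than substituted into the implementation.

The assumptions this rests on, and what happens when they fail:

* **The device lies on the centerline.** A guidewire can hug the vessel
  wall, so the intrinsic error is bounded by the vessel radius (about
  3.2 mm for a common carotid artery, the package's default branch
  radius). The method cannot do better than this bound without a model
  of the device's intravascular position.
* **The registration is correct.** The tree must be in X-ray
  coordinates before localization; `localize()` deliberately does not
  check frames, because no reliable runtime check exists. Registration
  error propagates directly into localization error.
* **The anatomy matches the pre-procedural model.** Vessel deformation
  between CT and intervention is not modeled; the localizer can only
  return points of the given tree.
* **Rays and centerlines are transverse.** When a centerline segment
  runs nearly parallel to the projection direction, or two branches
  superimpose, many candidates have near-equal objectives. The package
  detects (ambiguity flag) and regularizes (continuity restriction)
  rather than guessing.

## Coordinate and camera conventions

Right-handed system with origin at the iso-center: +x patient-left,
+y posterior (source-to-detector at identity angulation), +z cranial.
The primary angulation (LAO positive) rotates about +z and is applied
before the secondary angulation (cranial positive) about the rotated
x-axis; established C-arm camera descriptions do not fix one universal
convention, so this one is declared once and every test derives from
it. At identity angulation the source sits at $(0,-\mathrm{SOD},0)$ and
the detector center at $(0,\mathrm{SID}-\mathrm{SOD},0)$. Pixels are
0-based at pixel centers, with the detector center pixel
$((\mathrm{rows}-1)/2,(\mathrm{cols}-1)/2)$ on the central ray, which
keeps the identity cases exactly testable and avoids half-pixel drift.
Lengths are millimetres; interface angles are degrees. An optional
table-offset vector shifts the iso-center; residual offsets are
otherwise absorbed by registration.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| resampling spacing | 0.5 | mm | The localizer returns sampled points, so half the spacing is the sampling contribution to 3D error (0.25 mm). Spacing should stay below the projection pixel footprint at the iso-center (≈ 0.28 mm for 0.37 mm pixels at SID/SOD = 1000/750); 0.5 mm keeps the sampling term comparable to the pixel term without inflating candidate counts. |
| continuity window | 10 | mm (geodesic) | Must exceed the device's inter-frame travel (sub-millimetre to a few mm at fluoroscopy frame rates) while staying below the along-tree distance to superimposed branches (typically tens of mm). |
| ambiguity tolerance | 1 | % of the objective | Flags near-ties on other branches; an absolute floor equivalent to a 10⁻⁶ mm perpendicular distance catches exact ties that a relative test on a near-zero minimum would miss. |
| template size | 21 × 21 | px | Covers a marker blob of a few pixels sigma with background margin. |
| search radius | 20 | px | Upper bound on per-frame image motion. |
| sub-pixel refinement | off | — | 3-point parabolic interpolation around the correlation peak; enable for noisy sequences (see below). |

The continuity window is *geodesic* (along the tree, through branch
junctions) rather than Euclidean. This is the mechanism that excludes
wrong-branch candidates: branches that overlap in projection are often
close in 3D space but far along the vessel tree, so a Euclidean window
would readmit exactly the candidates the restriction exists to remove.
Whether the first frame is localized over the full tree or fixed to an
operator-approved initial position is an explicit `init` argument,
since no automatic rule can resolve a genuinely ambiguous first frame.

## Registration and the epipolar reference

Clinical workflows provide about three fiducials, which under-determine
a 12-parameter affine map; the default registration mode is therefore
*similarity* (rotation, translation, isotropic scale), exactly
determined by three non-collinear points via the SVD-based orthogonal
Procrustes construction. Affine remains available for four or more
non-coplanar fiducials. Reflections are rejected
($\det R = +1$ enforced) since anatomy cannot mirror. Reference 3D
positions for validation come from two-view epipolar triangulation: the
midpoint of the common perpendicular between the two back-projection
rays, with the segment length reported as the `gap` quality measure.
View pairs below 5° separation are refused and below 30° warned, since
the reconstruction error scales with the inverse sine of the
separation.

## The synthetic phantom

`make_phantom()` generates a circular aortic arch (radius 35 mm, span
180°, plane tilted 15° for genuine depth variation) with a straight
carotid-like branch (80 mm, radius 3.2 mm) attached near the apex, and
markers at stated arc positions displaced radially from the centerline
by a stated offset in seeded random azimuths. The defaults — SOD
750 mm, SID 1000 mm, 512² detector at 0.37 mm pixels — are plausible
for a TAVR-style acquisition, and all are configurable; none are
claimed to reproduce any particular physical phantom.

What the generator emulates: projective geometry, magnification, pixel
quantization, manual picking noise (Gaussian, in pixels), off-center
devices (radial offsets up to the vessel radius), marker blobs with
additive Gaussian image noise, and superimposed-branch constellations
(`make_superimposed_scene()` places a ghost branch exactly on the
projection rays of the true branch). What it does not emulate: X-ray
physics (scatter, beam hardening, heel effect), anatomical deformation,
cardiac or respiratory motion, background clutter from other devices or
contrast, and calibration error in the camera model itself. Passing
tests therefore demonstrate correctness of the geometry and the
algorithmic behavior under controlled violations of the centerline
assumption — not clinical accuracy, which depends on registration and
model fidelity that only real data can probe.

Problem sizes used in the shipped experiments: trees of a few hundred
candidate points (the package's flattened phantom has ≈ 380 at 0.5 mm),
1000 randomized scenes for the optimality check, 50 phantom seeds for
the radial-offset bound, 200 seeds for registration noise, and 60-frame
tracking sequences on a 192² raster — small enough to run in seconds,
large enough that every stochastic claim is averaged over many draws.

## Numerical choices and degenerate inputs

* Ties in the argmin are broken by smaller perpendicular distance, then
  lower (branch, index) in tree declaration order — the objective has no
  natural tie-break and determinism requires one.
* Projections require the point strictly between source and detector;
  points at or behind the source raise a degenerate-projection error
  rather than returning a mirrored pixel.
* Triangulation rejects ray pairs within 10⁻⁶ of parallel (reporting
  the inter-ray angle); collinear fiducials (rank < 2 after centering)
  and coplanar affine configurations (rank < 4) raise rank errors.
* Resampling preserves branch endpoints exactly, interpolates
  coordinates and radii linearly in arc length, and remaps junction
  attachment indices to the nearest resampled arc position. The final
  segment of each branch may be shorter than the spacing.
* Branch junction edges carry the Euclidean gap between the child's
  first point and the parent attachment point (with a tiny positive
  floor so the graph stays weighted-connected when they coincide).
* All seeded draws go through an internal sub-seed derivation that
  stays inside R's 32-bit integer range, and generation restores the
  caller's RNG state.

## Tracking and the template choice

The tracker is zero-mean normalized cross-correlation of a fixed
template over an integer search window — normalized for illumination
robustness, fixed to avoid drift, with ties broken toward the smallest
displacement. Two refinements matter in low-dose conditions. First,
sub-pixel refinement (parabolic fit around the peak) removes the
half-pixel quantization floor. Second, the template source matters
more than its size: a patch cut from the first *noisy* frame carries
that frame's noise realization into every subsequent correlation,
producing a persistent sub-pixel to ≈ 1 px bias that neither frame
averaging nor smoothing removes (the bias lives in the template's
low-frequency noise components, exactly where the blob's energy is).
Supplying a designed appearance model instead — `gaussian_template()`
for blob-like radio-opaque markers, via the `template` argument of
`init_track()` — is classical matched filtering and eliminates the
bias; at a peak signal-to-noise ratio of 5 it brings the fraction of
frames tracked within 1 px from roughly 70 % (noisy patch template) to
effectively 100 %. The patch template remains the default because it
needs no appearance model; the matched-filter configuration is the
recommended one for known marker types.

## Known limitations

* Accuracy is intrinsically floored by the device's distance from the
  centerline (vessel radius) and by registration error; neither is
  visible to the algorithm at run time.
* The continuity restriction assumes the device genuinely moves
  continuously; retraction-and-reinsertion or frame drops larger than
  the window require re-initialization.
* Depth errors along the ray are invisible in the 2D iso-center-plane
  metric; only a 3D reference (triangulation on phantoms) measures
  them.
* The CSV and VTK centerline formats carry no branch topology; only
  the JSON dialect round-trips parent/attachment structure.
* Per-frame geometries are supported throughout, but the tracker
  assumes a static gantry within a tracked sequence (template
  appearance is not re-projected under gantry motion).
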