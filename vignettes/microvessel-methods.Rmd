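---
title: "Quantifying microvascular networks in 3D: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvascular networks in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package measures

Perfusable microvascular networks grown in microfluidic chips are imaged
by confocal microscopy after perfusing a fluorescent probe: the signal
fills the vessel *lumen*, so a z-stack is a direct 3D picture of the
fluid-accessible network. `microvessel` turns such a stack into
quantitative morphology and a first-order estimate of intravascular
flow:

1. **Preprocessing** — the z step of a confocal stack (typically ~5 μm)
   is several times the in-plane pixel size (~1 μm). `isotropize()`
   interpolates linearly along z onto cubic voxels; `downsample()`
   optionally decimates (one voxel out of *n* per axis) to cut cost on
   large chips.
2. **Segmentation** — `segment_active_contour()` produces the boolean
   lumen mask with a morphological two-phase active contour (see below);
   externally produced masks (e.g. from a trained neural network) enter
   through `load_mask()`.
3. **Vertical alignment** — `fit_plane()` + `align_vertical()` remove
   the small tilt introduced by chip/microscope misalignment with a
   rigid rotation.
4. **Skeletonization** — `skeletonize()` reduces the mask to one-voxel
   centerlines by topology-preserving thinning.
5. **Branch processing** — `build_graph()` clusters junction voxels into
   nodes and traces branches; `prune_short_branches()` removes stubs;
   `extend_tips()` restores thinning's tip retraction; `smooth_branch()`
   replaces the voxel staircase with a spline.
6. **Morphometry** — `morphometry()` computes per-branch length,
   tortuosity, cross-section radii, eccentricity and lateral area, and
   network summaries including the surface-over-volume ratio (S/V).
7. **Flow estimation** — `flow_problem()` + `solve_flow()` solve the
   Poiseuille/mass-conservation network system for branch flow rates,
   velocities and wall shear stresses under imposed side pressures, with
   analytic (`uncertainty_analytic()`) and Monte-Carlo
   (`uncertainty_monte_carlo()`) propagation of radius uncertainty.

`run_pipeline()` orchestrates all stages from a single config and
persists every artifact plus a provenance log. Everything is validated
end-to-end on synthetic phantoms (`phantom_spec()`, `render_phantom()`,
`make_reference_network()`) whose ground truth is analytic.

## Definitions and conventions

- **Tortuosity** is branch arc length over the start-to-end chord, so a
  perfectly straight vessel scores 1 and values grow with winding. (The
  inverse convention, chord over length, appears in parts of the
  literature; we use length/chord because it makes 1 a hard lower bound
  and matches the in-vivo indices we compare against.)
- **Radius**: at `n_r` equidistant arc-length stations the mask is
  sliced perpendicular to the centerline; the radius is half the
  *equivalent diameter* `2*sqrt(A/pi)` of the in-plane connected region
  containing the centerline point. In-vitro lumina are elliptical, so
  this equals `sqrt(a*b)` for semi-axes `a >= b`. `n_r = 3` is the
  default; `n_r = 1` (mid-station only) and length-weighted network
  averaging are available because the averaging convention measurably
  changes network means.
- **Eccentricity**: an ellipse is fitted to each cross-section boundary
  by direct least squares (Halir–Flusser), with a second-moment fallback
  for degenerate fits. The default index is the mean axis ratio `b/a` —
  1 for a circular vessel, smaller for flatter ones — which makes
  "close to 1 = circular" read naturally alongside the radius. The
  classical eccentricity `sqrt(1-(b/a)^2)` (0 for a circle) is available
  via `convention = "classical"`. Both are well-defined; only the
  direction of the scale differs.
- **Lateral area** uses the frustum sum `pi (r_k + r_{k+1}) ds` between
  stations, with the stretches outside the first/last station counted
  as cylinders, so a constant-radius branch gives exactly `2 pi r L`.
- **S/V** is total lateral area over *extravascular* volume (analysis
  box minus lumen), reported in mm²/mm³ — the quantity that governs
  exchange in transport models.
- Axes are (x, y, z) with z the TIFF page axis; physical coordinates are
  voxel-center, `coord = (index-1) * spacing`, in micrometres.

## Segmentation: morphological two-phase active contour

The classical two-phase region energy is minimized pointwise by
assigning each voxel to the nearer of the two phase means; the curvature
term is approximated by a majority filter. We use the 7-cell
(face-neighbor) majority rather than the full 3×3×3 box because box
majorities systematically erode thin, highly curved structures — on
5-voxel-radius tubes the box filter loses ~6% of the lumen volume per
run while the face-neighborhood variant stays within 0.3%. Iteration
stops at the first fixed point (typically < 10 sweeps). Otsu's threshold
initializes the contour by default, making the whole stage deterministic
and invariant to affine intensity rescaling. There is no denoising
stage: artifacts must be controlled at acquisition, and `downsample()`
doubles as mild noise suppression.

## Skeletonization and its artifacts

`skeletonize()` implements parallel directional thinning in the (26, 6)
digital topology: each pass visits the six face directions and deletes
*simple* border voxels — the Malandain–Bertrand characterization
(exactly one 26-component of foreground neighbors, exactly one
6-component of background in the 18-neighborhood touching a face
neighbor) guarantees connectivity, tunnels and cavities are untouched —
with a sequential re-check inside each sub-pass. Line ends are
preserved. Symmetric erosion from opposite faces keeps the curve
centered (within one voxel on straight tubes of radius 3–30 voxels) and
collapses the medial *sheet* of a flattened (elliptical) lumen into a
curve.

Two artifacts are inherent to any thinning and are handled explicitly
rather than ignored:

- **Tip retraction and claws.** Free tube ends retract by roughly one
  vessel radius, and on flattened lumina the last few skeleton voxels
  can bend toward a cap corner. `extend_tips()` trims a terminal branch
  back to where its local tangent last agreed (within 40°) with the
  pre-tip direction, then marches straight along that direction to the
  lumen boundary in half-voxel steps. Smoothly curved ends are not
  trimmed, so arc length and tortuosity of curved branches survive; on
  phantoms this restores total length to within ~1.5% of truth.
- **Spurs and micro-loops.** Junction regions shed short side spurs and
  occasionally tiny self-loops. `prune_short_branches()` removes
  terminal branches and self-loops below a length threshold and then
  dissolves pass-through (degree-2) junctions; interior branches are
  never removed. A threshold of ~2–5 voxels is appropriate; the pipeline
  default is 0 (off) so nothing is discarded silently.

Junction voxel clumps (≥3 skeleton neighbors) are clustered by
26-connectivity into a single node at their centroid; the connectivity
order and the clustering rule are fixed conventions of this
implementation, since raw thinning output does not define them.

## Branch splines and length

Digitized centerlines overestimate length (a 45° staircase by √2).
`smooth_branch()` pre-smooths interior points with a centered moving
average (half-window `smoothing`, endpoints pinned) and interpolates
with a natural cubic spline against the chord-length parameter,
resampled densely. `smoothing = 0` interpolates every point exactly.
The default half-window of 2 was calibrated once on the 45° staircase
fixture (length recovered within 1%) and recovers a digitized
quarter-circle's arc length within 2%. We pin endpoints (rather than
use a penalized smoothing spline) because branch ends must coincide with
graph nodes exactly.

Radius stations are inset from the branch ends by 1.5 local radii
(estimated from the Euclidean distance transform at the branch
midpoint, capped at a quarter of the branch length). This single rule
keeps end stations clear of junction blobs, of oblique cuts through end
caps, and of the rectified-tip region; a fixed half-voxel inset proved
too fragile on wide or flattened vessels.

## Flow model

Each branch is an ideal cylinder with hydraulic resistance
`R = 128 mu L / (pi D^4)`; every branch satisfies `p_a - p_b = R Q` and
every interior node conserves mass. The solver eliminates the branch
equations and solves the sparse nodal conductance system (Matrix
package); the full `(n_branch + n_nodes)` formulation is retained in the
test suite as an independent dense oracle, which the solver matches to
1e-10 relative on random networks. Boundary conditions mimic the
chip: constant pressure on nodes within a margin of the two opposite
faces of the analysis box (or an explicit node/pressure table).
Dead-end branches carry zero flow, consistent with neglecting
transmural filtration. Velocity is `Q / (pi r^2)` and wall shear stress
`tau = 4 mu |v| / r`; elliptical cross-sections are treated as circular
with the equivalent radius for flow purposes, a simplification with
minor effect for steady flow. Viscosity defaults to 1.0 mPa·s (aqueous
culture medium); red-blood-cell rheology (Fåhræus–Lindqvist,
plasma skimming) is out of scope, but `export_3d1d_inputs()` writes the
node/segment tables a coupled 3D–1D filtration solver needs.

Radius uncertainty propagates analytically as `dv = 2 v dr / r` and
`dWSS = tau dr / r` at fixed pressure drop, or by Monte-Carlo:
`uncertainty_monte_carlo()` redraws every branch radius from
`Normal(r, dr)` (truncated positive, redraws counted), re-evaluates the
network per draw, and reports distributions. Single-vessel problems use
the vectorized closed form, so 10⁶ draws take about a second. Normality
is assessed by Shapiro–Wilk on the first `min(n, 5000)` draws: with
millions of samples any omnibus test rejects microscopic departures, so
an unbounded test would be uninformative. WSS is linear in r, hence
Gaussian; velocity is quadratic in r, hence right-skewed — its square
root is Gaussian again. These shape statements are exactly what the
seeded tests check.

## Phantoms: what they emulate and what they do not

The phantom generator renders tube networks with known centerlines,
elliptical cross-sections (major axis horizontal, as observed on-chip),
two-level intensities, and optional Gaussian or Poisson noise. The
lumen in/out test is exact (no anti-aliasing), so truth values — length
by quadrature, tortuosity, Ramanujan perimeter × length for lateral
area — are analytic; noise only ever touches intensities, never the
truth mask. Junctions are realized as overlapping tubes without fillet
modelling. `make_reference_network()` lays a lattice (or a jittered,
randomly thinned variant) in a 450 × 450 × 100 μm slab at 150 μm pitch
and solves for the tube radius that hits a target S/V of 4.5 mm²/mm³ —
the density scale of vasculogenic chips — giving branch lengths of
~150 μm and radii of ~8 μm. These sizes keep a full pipeline run on one
CPU in seconds while leaving every metric's recovery measurable; radius
recovery is additionally tested out to 30-voxel tubes.

Phantoms deliberately do **not** model the point-spread function, depth
attenuation, autofluorescence, non-perfused network fragments, or
vessel wall signal. Passing phantoms therefore demonstrates that the
geometry and flow machinery is correct and self-consistent, not that
segmentation is robust to every real acquisition artifact; for real
data the external-mask route exists precisely so a better segmenter can
be swapped in without touching the rest of the pipeline.

## Numerical choices and degenerate inputs

- Connectivity is 26 for foreground, 6 for background, everywhere.
- Ties between equal-size components in `keep_largest_component()` go to
  the component first reached in column-major scan order.
- Closed loops have undefined tortuosity (`NaN`, with a warning).
- Cross-section stations with an empty slice are skipped with a warning;
  a branch whose stations are all empty is an error (mask and skeleton
  disagree).
- `align_vertical()` skips rotation below 0.05° of fitted tilt;
  rotation uses nearest-neighbor resampling to preserve binarity and
  drops out-of-bounds voxels with a count.
- Uniform-intensity volumes are rejected by segmentation ("no separable
  phases"); empty masks are rejected by all downstream stages.
- The 2D (z-projection) mode reuses the same thinning on a single-slice
  volume (where the simple-point test reduces to the 2D one) and takes
  radii from the 2D distance transform at the centerline — the estimate
  a planar analysis has access to, and the reason projected radii of
  flat elliptical vessels read systematically wide while projected
  lengths can only shrink.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on synthetic
inputs: single tubes of 60–200 μm at 1–2 μm voxels, the 12-branch
reference lattice (~2.5M voxels), random flow networks of ≤12 branches,
and the 10⁶-draw single-vessel Monte-Carlo. A full pipeline run on the
reference lattice takes a few seconds on one CPU; the whole suite a few
minutes.

## Known limitations

- Thinning-based centerlines wander up to ~1 voxel inside very flat
  lumina; radius stations compensate with wide-chord tangents, but
  per-station eccentricity near junctions is noisy.
- Tip rectification assumes a roughly straight final stretch; a vessel
  that genuinely hooks within ~2 radii of its free end would be
  straightened slightly.
- The flow model ignores filtration, hematocrit effects and the actual
  elliptical conduit shape; it is a Poiseuille estimate, not a CFD
  result.
- Decimation-based downsampling cuts off vessels thinner than the new
  voxel size; that is the documented trade-off, not a bug.
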