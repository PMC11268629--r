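---
title: "Geometry-based picking: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based picking: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopick)
```

cryopick converts sparse manual annotations of cryo-electron tomograms into
dense, regularly spaced particle poses, surface models, straightened
volumes and segmentations. This vignette documents the underlying models,
the parameters that matter, the numerical decisions taken where the design
was genuinely open, and what the synthetic test data does and does not
establish about real tomograms.

## Conventions

Particle positions are in voxel units of the source tomogram, axis order
(x, y, z), zero-based, matching the particle file formats. Image arrays
are R column-major indexed `[x, y, z]` — x fastest in memory, the on-disk
order of MRC — so a position indexes its voxel directly (plus one for R's
1-based indexing). Orientation matrices map reference-frame basis vectors
onto particle basis vectors (column *i* is the particle's *i*-th axis in
tomogram coordinates); `particle_to_reference()` gives the transposed
view. An unknown pixel spacing is encoded as 0 and propagated, never
guessed: silently assumed units are the classic interoperability failure
in this field.

## Parametric splines and arc-length sampling

`fit_spline3d()` fits one B-spline per coordinate against the normalised
cumulative chord-length parameter of the input points, with a clamped knot
vector whose interior knots are de Boor averages of the data parameters —
this guarantees the Schoenberg–Whitney conditions, so interpolation
(`smoothing = 0`) is a well-posed square linear system. The `order`
parameter is the polynomial degree (1–5, default 3, cubic); it is demoted
to M − 1 when only M points are given, so two points always yield the
chord.

**Smoothing.** The smoothing semantics were an open choice (interactive
picking tools expose a smoothing knob without defining it). We use a
penalised least-squares fit: minimise the squared residual plus
`smoothing` times the squared second differences of the control points
(the P-spline penalty). `smoothing = 0` interpolates exactly; increasing
values shrink the curve towards a straight fit. The penalty on control
points rather than on the integrated second derivative keeps the fit a
small dense solve at any degree, including degree 1.

**Arc length.** The curve is densely sampled at
`max(1000, 10·M·(degree+1))` uniform parameter values; cumulative chordal
sums give a monotone parameter → length table, inverted by linear
interpolation. `sample_equidistant(spacing)` then places
`K = max(2, round(L/spacing) + 1)` samples at arc lengths `j·L/(K−1)`:
the spacing is adjusted so that samples divide the total length exactly,
because downstream (helical lattices, surface grids) exact *equidistance*
matters more than the nominal spacing value. Consecutive Euclidean
distances agree with the arc-length steps to well under 0.1 % when the
local curvature radius is large against the spacing (roughly spacing <
R/10); at tighter bends the chord/arc distinction is real and no sampling
scheme can remove it.

**Moving frames.** Helical lattices and surface poses need a continuous
frame along a curve, which no format defines. We use rotation-minimising
frames computed by the double-reflection method, seeded at t = 0 with a
deterministic normal (the coordinate axis with the smallest tangent
component, projected into the normal plane, so a straight +z segment gets
the identity frame). Each frame is re-orthogonalised during transport;
frames are proper rotations with the unit tangent as local Z, and carry no
twist beyond what the curve imposes. A zero tangent (coincident picks at a
curve end) raises a numerical error naming the parameter location rather
than returning an arbitrary frame.

## Helical filaments

`generate_helical_poses()` implements the five-step filament procedure:
spline through the picks; equidistant samples at the **rise** ρ (voxels,
measured along the filament axis — the helical-nomenclature convention —
not along the helical path); per-sample orientation `F_j · Rz(j·twist)`
with twist in degrees accumulated from the filament start (index 0); a
**radius** r (voxels) shifts each pose along its twisted local X axis,
which is what produces a helical point pattern; **symmetry** n (cyclic
group Cn) replicates each pose by additional local-Z rotations of 360/n
degrees, rotating both offset and orientation about the axis point so
the lattice stays consistent for averaging. Where the twist phase
originates is not defined by any convention we know of; phasing from the
filament start is the minimal deterministic choice, and a refinement
package will absorb any global phase anyway.

## Spline-grid surfaces

`build_surface_grid()` runs the eight-step construction: per-strip splines
(steps 1–2), equidistant strip samples at `spacing` (step 3), integer
alignment and padding (step 4), column splines across the strips (step 5),
their equidistant resampling into the final grid (step 6), row splines
through the final grid (step 7), and orientation frames from the two
tangent families (step 8).

Decisions taken where the procedure is underdetermined:

- **Alignment** searches integer index shifts only (brute force over all
  shifts with ≥ 2 index-matched points), minimising the *mean* matched
  distance — a sum would favour minimal overlap. Ties break towards the
  smaller absolute shift, then the smaller signed shift, for determinism.
- **Padding** extends each strip to the common rectangle width by linear
  extrapolation of its terminal segment. Extrapolated nodes keep the
  column splines smooth but are flagged in `padded_mask`; they support the
  fit yet are excluded from `surface_poses()` by default, because they are
  not annotated surface.
- **Rectangularity of the resampled grid.** Column splines generally have
  different lengths, but a grid must share one row count: we set it from
  the *mean* column length (`max(2, round(mean(L)/spacing) + 1)`) and
  sample every column at equal fractions of its own length. On gently
  varying surfaces the realised spacing stays within a few percent of the
  request; on strongly skewed grids it degrades gracefully instead of
  breaking the lattice.
- **Normal signs** are arbitrary pointwise; we seed the sign from the
  tangent cross product at the first unpadded node and propagate it across
  the grid by neighbour continuity, so a grid never mixes inward and
  outward normals. Frames use local Z = normal and Gram–Schmidt of the
  tangents for X and Y.
- **Padded-mask propagation**: a resampled node counts as padded if any
  extrapolated strip node influences its neighbourhood on the column
  spline (interpolated mask > 0) — conservative by construction.

Collinear degenerate input (all picks on one line) fails with an error
naming the construction step, as does any strip whose spline cannot be
fit. Strongly irregular surfaces — membranes with invaginations that fold
over in Z — deform the grid; the error contract is guaranteed there, a
meaningful lattice is not.

## Surface-guided resampling

`resample_along_surface()` samples the volume by trilinear interpolation
at `node + offset·normal` for `W = 2·floor(thickness/(2·step)) + 1`
offsets. W is forced odd so the annotated surface is exactly the central
slice and `thickness` (voxels) is symmetric about it; `step` (voxels) sets
the normal-axis sampling interval and multiplies the output pixel spacing.
The output array is (W, U, V) — normal axis first, so "average along Z" is
a mean over axis 1. Out-of-volume samples are filled with the volume mean,
which avoids contrast artefacts in projections, and a companion `valid`
mask records real samples so `project_mean()` can ignore the filled
voxels; quantification should always consult the mask.

## Label interpolation

`signed_distance_field()` is positive inside a mask (Euclidean distance to
the nearest outside voxel, via the distance transform), negative outside,
clipped to ±cap with cap = the sum of the slice dimensions — an
unreachable distance, so empty slices behave as "label absent" with finite
arithmetic. `interpolate_labels()` treats a slice as annotated when it
contains any nonzero label; between consecutive annotated slices a < b,
each label's field at position x is the standard linear interpolation
`((b−x)·SDF_a + (x−a)·SDF_b)/(b−a)`. Weighting each slice by its own
distance would extrapolate rather than interpolate; the linear reading is
the self-consistent one. Membership is strictly `field > 0`; competing
labels resolve to the larger field (ties to the lower label id, for
determinism). Annotated slices pass through unchanged and nothing is
extrapolated beyond the outermost annotated slices.

A label present on only one of two bounding slices shrinks toward nothing
across the gap (its absent-side SDF is the constant −cap). That is a
choice, not a theorem; it matches the intuition that an object annotated
on one slice and absent on the next ends somewhere in between. Thin
structures — filaments, single-voxel sheets — interpolate poorly under any
SDF scheme, since their fields are negative almost everywhere.

## Image operations

`convolve2d()` is the centred weighted average with nearest-border
replication — the semantics of clamped GPU texture sampling, which is the
mechanism this operation mirrors. It uses the cross-correlation convention
(kernel not flipped; the impulse response is the point-reflected kernel),
stated and tested rather than implicit. `gaussian_filter()` applies the
sampled 1D Gaussian separably per axis with the same clamping, which is
mathematically identical to the dense N-D kernel under clamped sampling;
the automatic kernel size is `2·ceil(3σ)+1`. `bandpass_filter()` masks the
FFT radially in cycles/image with raised-cosine transitions (default
width 2 frequency pixels) to limit ringing, and removes DC whenever
`low > 0`. `power_spectrum()` uses the unnormalised forward FFT, so
`sum(power) = N·sum(image²)` (Parseval) pins the convention; the zero
frequency is centred, and `log_power()` is the display transform.

## File formats

STAR reading supports both Relion origin dialects: Angstrom origins
(`rlnOriginXAngst`, converted through the optics-group pixel size) take
precedence; pixel origins (`rlnOriginX`, the 3.0 dialect) are honoured
when no optics information exists. Unrecognised columns ride along as
features and are written back. The Dynamo TBL layout is fixed to the
documented 1-indexed columns (1 tag, 4–6 shifts, 7–9 tdrot/tilt/narot,
20 volume id, 24–26 coordinates); shorter tables are zero-padded on read.
Both text formats are written at 6 decimals, which bounds round-trip
errors at 5·10⁻⁷ voxel in position and ~10⁻⁸ in orientation entries.
MRC is written as mode 2 (32-bit float, little-endian) with the voxel
size header set; modes 0/1/2/6 are read. TIFF carries no spacing and its
32-bit storage quantises values in [0, 1] at 2⁻³²; EM is read-only.
EMAN2 `.json`/`.hdf` and Relion-4 tomography tables are out of scope in
this version. The Euler conventions are defined in `euler_to_matrix()`
relative to the package's reference→particle semantics; at gimbal lock
(tilt 0 or 180°) the first angle is zeroed and the third absorbs the
in-plane rotation, and round trips are exact away from lock.

## Synthetic data: what it shows and what it does not

The fixture generators define the test conditions: `make_helix_volume()`
(48×48×64 voxels, rise 6, twist 30°, radius 8, Gaussian blobs of σ = 1.5,
optional additive Gaussian noise) emulates a regular helical filament;
`make_membrane_fixture()` renders tilted-plane, sinusoidal-sheet and
cylinder (radius 50) membranes as Gaussian shells with per-slice pick
strips and analytic normals; `make_label_stack()` produces sparse disks
and squares with known radii. Sizes were chosen as the smallest volumes
that hold the analytic shapes with realistic margins; all randomness
(noise, pick jitter) is seed-controlled and scoped.

These fixtures have exact ground truth and none of the pathologies of real
tomograms: no missing wedge, no contrast transfer function, no crowding,
no picking bias, no strongly irregular membranes. Passing tests therefore
establish that the *geometry* — equidistance, lattice structure, normals,
field interpolation, format arithmetic — is implemented correctly, not
that picking will succeed on any particular specimen. The test problem
sizes (64³ volumes, grids of a few hundred nodes, 10⁴ rotation round
trips) were chosen so the whole suite completes in well under a minute
per module while still exercising every code path at meaningful scale.

## Known limitations

- Splines are open; closed/periodic filaments (rings) are approximated by
  repeating the first point, which leaves a small seam in the frame field.
- Only cyclic (Cn) symmetry; no dihedral or point groups.
- Surface grids assume strips that advance monotonically slice to slice;
  folded or branching membranes deform the grid.
- SDF interpolation is volumetric; thin labels need a different scheme.
- TIFF values outside [0, 1] are not representable by the writer; MRC is
  the lossless route.
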