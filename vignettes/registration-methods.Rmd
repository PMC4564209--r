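---
title: "Correlation-ratio affine and local-correlation deformable registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-ratio affine and local-correlation deformable registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`voxalign` registers 3-D scalar brain volumes in two stages: a global affine
search driven by the correlation ratio, and an optional deformable
refinement driven by the local squared cross-correlation. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic phantom does and does not tell you
about behaviour on real data.

## Coordinate conventions

A `volume` stores a 3-D array plus voxel spacing (mm) and a world origin
(mm). Voxel centers sit at `index * spacing + origin` with 0-based indices;
every transform and displacement is expressed in this world (mm) frame, so
anisotropic voxels never leak into transform parameters. Affine transforms
map reference world coordinates into moving world coordinates; a
displacement field u makes a warped image sample its source at x + u(x).
Trilinear samples outside the source grid clamp to the nearest edge value;
the *overlap region* used by the similarity metrics is handled separately,
as the set of reference voxels whose mapped position falls inside the moving
volume's voxel-center span.

## The correlation ratio and its sorted-index evaluation

For reference *I* and transformed moving image *J_T*, the correlation ratio

$$\eta(J_T \mid I) = 1 - \frac{1}{N\sigma^2}\sum_i N_i \sigma_i^2$$

measures how much of J_T's variance (σ² over the N overlap voxels) is
explained by conditioning on I's intensity bins (σ_i² within the N_i voxels
of bin i). It is asymmetric, needs no joint 2-D histogram, and ranges from 0
(no functional dependence) to 1 (deterministic dependence), which makes it a
robust cost for coarse, low-resolution search stages.

Evaluation follows a sort-then-segment scheme. The reference level is binned
once per resolution stage (uniform bins over the in-mask min–max; the
maximum maps into the last bin; a constant image is flagged degenerate);
the voxels are stably sorted by bin index so each bin occupies a contiguous
segment whose start/end positions are recorded. Per-bin count, sum and sum
of squares of J_T are then accumulated by traversing segments, and η falls
out of a final reduction. Three contracts make this path trustworthy:

* **Partition invariance** — bins may be grouped into any number of
  partitions, processed independently and merged; the result is identical.
  This is the serial equivalence contract for a per-bin parallel reduction.
* **Oracle equivalence** — a naive direct-grouping implementation
  (`correlation_ratio_direct`) agrees with the segmented path to 1e-10
  relative on randomized instances.
* **Reuse** — the sorted index depends only on the reference level, so it is
  built exactly once per stage and reused by every candidate transform (the
  registration trace records the build count).

Bins with one voxel have zero conditional variance and contribute nothing;
empty bins are skipped; zero total variance or an empty overlap is an error
at the metric level and a sentinel worst cost (`Inf`) inside the search.
η is clamped to [0, 1] against roundoff.

## The affine search

`register_affine` resamples both volumes to 1 mm isotropic (trilinear,
output dimensions `ceiling(extent / target)`), builds an 8/4/2/1 mm pyramid
by successive 2×2×2 block averaging (mean-preserving, deterministic,
edge blocks truncated), and uses **256/n histogram bins at the n mm stage**
(32, 64, 128, 256).

* At 8 mm, a multistart grid over rotations (±45° in 15° steps per axis) and
  translations (±16 mm in 8 mm steps per axis, around the pose aligning the
  two volume centers) is evaluated; the best 3 candidates survive. The
  centre-aligned initial pose is always carried as an extra survivor: at
  8 mm the per-bin statistics are thin (few voxels per bin), and a grid
  winner can be an overfit pose whose small overlap happens to bin cleanly.
  For the same reason the cost returns its sentinel when the overlap covers
  less than 20% of the reference grid — a transform that throws away most
  of the image should never look good.
* Each finer stage locally optimizes the surviving candidates by
  derivative-free coordinate descent with step halving (initial step = the
  stage resolution in mm for translations, and that length divided by the
  half-extent of the volume for rotations, scales and shears; four halvings
  before termination) and passes the best forward. Accepted moves strictly
  decrease the cost, so each local trace is non-increasing by construction.

Degrees of freedom are 6 (rigid), 9 (+scales) or 12 (full affine, the
default, matching common practice for brain-to-brain initialization);
rotations compose as Rx·Ry·Rz about the reference volume's physical center,
and parameters round-trip through the matrix via a sign-fixed QR
decomposition. The multistart grid, the survivor count, and the
coordinate-descent termination rule are implementation choices — the method
family deliberately pins down only the pyramid, the bin rule and the metric;
any optimizer with the non-increasing-cost contract is conformant.

## The local squared cross-correlation

Around every voxel, over a (2r+1)³ window (r in voxels, default 5 for
standalone CC maps, hard ceiling 8), the metric is CC = C²/(A·B) with A, B
the windowed centered sums of squares and C the centered cross-sum,
assembled from five window sums (ΣI, ΣJ, ΣI², ΣJ², ΣIJ). The expanded
A/B/C forms are evaluated literally and tested against their algebraic
simplifications (A = ΣI² − (ΣI)²/n, etc.) to 1e-9 relative.

Numerical choices:

* **Boundary**: edge replication, so n = (2r+1)³ is constant everywhere and
  the formulas stay literal at the border.
* **Degenerate patches**: where A·B ≤ eps (default 1e-12·n) a patch is
  numerically flat and carries no correlation signal; the voxel is marked
  invalid with CC = 0 rather than dividing by a vanishing denominator.
* **Range**: as a squared (unsigned) correlation CC lies in [0, 1] by
  Cauchy–Schwarz; it is clamped against roundoff. It is invariant under
  per-image affine intensity rescaling and symmetric in its two arguments.

The sums are computed separably by running prefix sums (add the entering
slab, drop the leaving one) — algebraically identical to fresh per-voxel
loops, and checked against a nested-loop oracle to 1e-8.

## The symmetric deformable refinement

`register_symmetric` is a deliberately simple symmetric scheme: two
half-way displacement fields φ1, φ2 warp the reference and the moving image
toward a common midpoint, and both are updated greedily to increase the
mean local CC. It is a surrogate for time-integrated velocity-field
(LDDMM-style) optimization: the metric is exact, the transform model is
not. Each step

1. warps both images through their current fields,
2. evaluates the CC map and the per-voxel derivative of C²/(AB) with
   respect to each image's value, carried through that image's spatial
   gradient (central differences),
3. Gaussian-smooths the raw update (default 3 mm), normalizes its largest
   displacement to half the step (default step 0.5 voxel — each half-way
   field takes half), adds it, and smooths the total fields (default
   1.5 mm),
4. accepts only if the mean CC increased; a rejected step halves the step
   length, and iteration stops when the step falls below 0.02 voxel.

The order *smooth first, then normalize* matters: normalizing the raw
point-wise force before smoothing lets a single sharp force spike set the
scale, and after smoothing the effective step shrinks by an order of
magnitude; the field then barely moves within any iteration budget.
Similarly, the total-field smoothing must stay small relative to the
per-step update smoothing, because it is re-applied at every accepted step
and its widths add in quadrature across iterations.

Accepted mean-CC values are recorded per pyramid level (default factors 2
then 1, by block averaging); the trace is non-decreasing within each level
by construction. Mean CC is *not* comparable across levels — the grid, the
window and the valid set all change — which is why the trace is reported
per level rather than as one flat vector. The default window radius for the
refinement is 3 voxels: at the 32³–64³ volumes this scheme targets, an
11³ window (r = 5) spans a third of the field of view and makes the update
direction nearly global, while r = 3 keeps it local; the metric functions
themselves accept any r ≤ 8.

The final warp of the moving image onto the reference grid composes the
inverse of φ1 (fixed-point iteration, 20 iterations or a residual below
1e-3 voxel) with φ2. Jacobian positivity is not enforced; the scheme relies
on small smoothed steps to stay well-behaved.

## The phantom: what it emulates, and what it does not

`make_phantom` builds a T1-like head: three nested ellipsoidal structures —
an outer scalp/skull-like shell, a bright cortex-like annulus, and a dim
ventricle-like core — with distinct piecewise-constant means
(60 / 110 / 25 on a zero background), additive Gaussian noise (default
2.2, i.e. 2% of the peak contrast), and an optional smooth multiplicative
bias field. The per-axis semi-axes differ and the core sits off-center, so
the shape has no rotational symmetry and planted rotations are identifiable.
Everything is reproducible bit-for-bit from the seed.

Planted ground truth comes in two forms. `apply_known_affine` resamples the
phantom through the inverse of a parameterized transform, so registering the
moved volume back to the original should recover exactly those parameters.
`apply_known_deformation` builds a smooth random field by Gaussian-filtering
white noise and rescaling each component's maximum to the requested
amplitude; the noise is smoothed with a *zero* boundary rather than edge
replication — replication concentrates the clamped kernel mass on single
boundary samples, inflating the variance at corners so severely that
max-normalization crushes the interior field to near zero; with zero
boundaries the field tapers at the edges and its maximum sits in the
interior. Amplitude is capped at half the smoothness to keep the warp
invertible in practice.

What passing on the phantom does *not* show: real MR intensities are not
piecewise constant (no texture, no partial-volume ramps), real noise is
Rician not Gaussian, real anatomy has far richer geometry than three
ellipsoids, and real scans carry orientation metadata this package only
passes through. Phantom results validate the algebra and the optimization
machinery, not clinical accuracy.

## Evaluation choices

`mad_volumes` is the mean absolute voxelwise difference; `jaccard` reports
per-label |A∩B|/|A∪B| over foreground labels plus their mean (background 0
excluded; a label present in only one volume scores 0; labels absent from
both are omitted). Labels are carried through recovered transforms by
nearest-neighbour resampling with out-of-extent voxels set to background.

Two MAD subtleties shape the bundled experiments. First, every resampling
blurs edges, so even warping a deformed volume back through the *exact*
inverse of the true field leaves a MAD floor at the structure boundaries of
a piecewise-constant phantom. Second, additive noise contributes its own
floor that no registration can remove. The deformable-improvement
experiment (amplitude 3 voxels, smoothness 8 voxels, 48³) therefore uses a
low-noise phantom (noise 0.5): at the affine experiment's 2% noise level,
the noise-plus-interpolation floor alone sits at about 45% of the
pre-registration MAD — i.e. at that noise the halving target is saturated
by effects no deformable model can influence, and the measurement would say
nothing about the registration. The affine recovery experiment keeps the
2% noise, where parameter recovery (not MAD) is the criterion.

## Problem sizes and determinism

The bundled tests run the full pipelines at deliberately modest sizes —
64³ for affine parameter recovery, 48³ for deformable improvement, 32³ and
below for properties and oracles — chosen so the whole suite exercises
every stage (multistart grid, four pyramid stages, coarse-to-fine
refinement) in a few minutes on one core. All pipelines are deterministic
given inputs and seed: the multistart grid is fixed, coordinate descent
breaks ties toward the first improving direction in a fixed parameter
order, sorting is stable with linear voxel order as tie-break, and every
random fixture flows from an explicit seed.

## Known limitations

* Only spacing and origin of the NIfTI header participate in computation;
  full qform/sform orientation handling, 4-D series and DICOM are out of
  scope.
* The deformable scheme is greedy and first-order: no velocity
  integration, no guaranteed diffeomorphism, no analytic CC gradient of the
  full windowed objective (the update uses the local per-voxel derivative).
* Mutual information and other cost functions, cost-function weighting and
  apodization, and 2-D registration are not implemented.
* The correlation ratio always bins the reference image as written; role
  swapping is left to the caller.
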