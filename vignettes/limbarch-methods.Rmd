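---
title: "limbarch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{limbarch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models behind `limbarch`, the tunable parameters
and why their defaults are what they are, what the synthetic phantoms do and
do not emulate, and the numerical choices made where the design was open.

# Geometry conventions

All geometry is metric (mm). A voxel grid with spacing $(d_x, d_y, d_z)$
places the center of voxel $(i, j, k)$ (1-based) at
$((i-\tfrac12)d_x, (j-\tfrac12)d_y, (k-\tfrac12)d_z)$, origin at the grid
corner, axes aligned. The rasterizers use a center-sampling rule — a voxel
is foreground exactly when its center lies inside the analytic solid — so
phantom generation is deterministic and closed-form areas/volumes are the
natural oracles for rasterization error.

# Volumetry

Volumes are voxel sums times the voxel volume, reported in cm³. Percent
change is the signed $100\,(V_\text{post}-V_\text{pre})/V_\text{pre}$;
tables additionally render the unsigned "loss of x% / gain of x%" phrasing
common in longitudinal reports. Compartment volumes are exact sums of their
member labels, and compartment-level change is recomputed from the summed
volumes (sum-then-ratio), never averaged from member percentages — the two
differ whenever members change disproportionately.

Pre/post stacks are aligned by a single bony landmark slice per stack:
stacks are shifted so the landmark slices coincide and trimmed to the common
z-range, with no resampling. This is deliberately minimal; expert visual
registration is not reproducible programmatically, and integer slice
alignment keeps volumes exactly comparable over the common coverage. Two
in-range landmarks always overlap on at least the landmark slice itself, so
an empty overlap can only arise from invalid indices, which are rejected
up front. Volumes are only meaningful over the trimmed common range when
acquisitions cover part of the limb.

# Fascia thickness

The deep fascia is modeled as a thin sheet appearing in each axial slice as
a narrow annular band. The pipeline per slice:

1. **Centerline.** The band is thinned to a one-pixel-wide topological
   skeleton. Guo–Hall two-subiteration thinning is used: unlike simpler
   schemes it produces minimal 8-connected chains without staircase pixels,
   which matters because the arclength estimator is a chain code.
   Spur branches are then pruned by iteratively deleting endpoint pixels
   (default `pruneLen = 5` passes) — closed loops have no endpoints and are
   untouched, while rasterization-induced side branches shorter than the
   pruning length disappear. On open structures (a ribbon rather than a
   loop) pruning also shortens the true ends, so `pruneLen = 0` is the
   right setting there.
2. **Thickness samples.** At every retained centerline pixel $x$,
   $t(x) = 2\,d(x)$ where $d$ is the Euclidean distance transform of the
   foreground (distance to the nearest background pixel,
   `EBImage::distmap`). On a true medial line both boundaries are
   equidistant, so the nearest-boundary distance is the half-thickness
   regardless of which side is nearer. The estimator's resolution behavior
   follows from pixel parity: when the band spans an even number of pixels
   the skeleton sits half a pixel off the true midline and the two
   half-pixel offsets cancel exactly; for odd widths they add one pixel.
   Averaged over the phases a curved band sweeps, the bias is a fraction of
   a pixel and shrinks proportionally with the pitch — the property the
   resolution tests check at 0.3 and 0.15 mm.
3. **Pooling.** Samples from all slices are pooled into the thickness
   distribution; summary statistics, fixed-width histograms (default bin
   0.05 mm — fine enough to resolve 0.1 mm-scale shifts at these pixel
   sizes without empty-bin noise) and pre/post shift reports (percent
   change of mean and median) follow. Fewer than `minSamples = 100` pooled
   samples is treated as an error advising finer resolution rather than a
   silently noisy estimate.

**Arclength.** The centerline arclength is a chain code: straight
(4-adjacent) and diagonal steps, each counted once, with a diagonal skipped
when the chain already runs through a shared 4-neighbor. Naive weights
$(1, \sqrt2)$ overestimate smooth curves systematically — averaged over
orientations a digital line costs ~5.5% extra — so the default weights are
the Kulpa-calibrated $(0.948, 1.340)$, which make a digitized circle's
length match $2\pi r$ to a fraction of a percent. The naive weights remain
available (`weights = "chain"`).

**Algebraic cross-check.** Independently of the medial axis,
$\bar t = V / (\bar L \times W)$, with $V$ the voxel-sum sheet volume,
$\bar L$ the mean per-slice centerline arclength over non-empty slices, and
$W$ the number of non-empty slices times the slice thickness. Empty slices
are excluded from $W$ (counting them would dilute the estimate with slices
contributing no volume or length). The two estimators share only the
centerline extraction, so their agreement is a meaningful internal
consistency check; the tests require 15% relative concordance on all
shipped phantoms.

**Dual-echo subtraction.** Fascia retains signal only at ultrashort echo
times; subtracting the short-TE from the ultrashort-TE image cancels
slowly-decaying tissue and isolates the sheet. The op is voxelwise
subtraction with negative clipping and optional [0, 1] rescale. A global
threshold segmenter on subtraction images is included for end-to-end demos
but is explicitly not a validated replacement for expert segmentation.

# Diffusion tensor stage

**Tensor fit.** With $S(g) = S_0 \exp(-b\, g^\top D g)$, taking logs makes
the fit linear in $(\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz},
D_{yz})$; ordinary least squares over all volumes solves it with one shared
design matrix, so the whole-image fit is a single matrix product. At least
7 volumes (6 directions plus a $b=0$ reference) are required; voxels with
any non-positive signal are flagged invalid rather than fitted. On
noiseless simulated data the fit is exact to machine precision, which the
round-trip tests exploit.

**Eigendecomposition.** FA/MD and the principal direction need per-voxel
eigensystems of symmetric 3×3 tensors. These are computed in closed form
(the trigonometric solution on the deviatoric part), vectorized over
voxels, with the principal eigenvector from the spectral projector
$(D-\lambda_2 I)(D-\lambda_3 I)$ and an `eigen()` fallback for
near-degenerate voxels. The closed form's eigenvalue accuracy is of order
$\sqrt{\varepsilon}$ relative, so "negative eigenvalue" flagging uses a
$10^{-6}$ relative threshold — a genuinely non-positive-definite fit from
corrupt data is orders of magnitude below that. The solver is cross-checked
against base `eigen()` on random tensors in the tests.

**Tractography.** Deterministic fixed-step Euler integration along the
principal eigenvector, bidirectional from seeds drawn uniformly inside the
mask (uniform voxel, then uniform position within it), nearest-voxel
direction lookup, eigenvector sign chosen for continuity with the previous
step. Stopping: mask exit, FA outside bounds, per-step turning angle
exceeded, or the length cap. Defaults — step 1 mm, max turn 30°/step, FA in
[0.05, 0.6], 1000 target tracts, 50 000 seed attempts, accepted lengths
5–200 mm — are conventional for muscle DTI; muscle FA sits around 0.2–0.3,
so the FA window rejects fat/fluid (low FA) and noise spikes (high FA). An
exhausted seed budget returns the partial set with a warning, never an
exception, since a partial tract sample is still analyzable.

**Extrapolation.** Tracts that stop short of the muscle boundary are
extended by fitting each coordinate as a cubic polynomial of arclength
(order 3: enough curvature for fascicle arcs without oscillation; the
abscissa is rescaled to $[-1,1]$ for conditioning) and marching the fitted
curve outward in half-step increments until it leaves the mask; the
crossing is then located by bisection to 0.1 mm. Each end may extend at
most 50% of the raw length; hitting that cap without finding the boundary
rejects the tract ("no-boundary"). The extrapolated polyline keeps the raw
points and appends fitted extensions, so the extrapolated length never
falls below the raw length.

**Inclusion filter.** Accepted fascicles must have reached the boundary,
satisfy extrapolated ≤ 1.3 × raw length (the "within 30% of the original
length" rule, read as bounding the total extension), and lie in 5–200 mm.
Every rejected tract carries exactly one reason, and the bookkeeping
satisfies tracked = accepted + rejected.

**Architecture.** Fascicle length is the polyline arclength of the
accepted tract; the fascicle vector is the unit chord from first to last
point (one vector per fascicle, not per-segment tangents); pennation is
$\arccos |v_f \cdot v_{loa}|$, the absolute value folding the arbitrary
tract orientation into [0°, 90°]. The line of action is the principal axis
of the voxel-coordinate covariance of the muscle mask, sign-oriented to
positive z; a planar or smaller region has no 3-D axis and errors.
PCSA = volume / mean fascicle length, stored so that
PCSA × mean length reproduces the volume identically.

# What the phantoms emulate — and what they do not

The generators reproduce the *measurement geometry* of a lower-limb
protocol, not anatomy:

* **Fascia tube** (`makeFasciaPhantom`): an irregular tube of base radius
  12.6 mm whose thickness and centerline radius carry low-order Fourier
  perturbations over angle, with a per-slice phase drift (tube twist,
  default 0.5 rad/slice in the pair generator) so slices are not copies of
  one another — a real fascia's cross-section varies along the leg, and the
  drift also decorrelates per-slice rasterization phases. Integer harmonics
  keep the analytic mean thickness exactly the base value. Defaults match
  a dual-echo UTE acquisition: 1.2 mm sheet, 0.3 mm in-plane pixels, 3 mm
  slices. A band resolved by fewer than 2 pixels sets a coarse-grid flag.
* **Limb masks** (`makeLimbPhantom`): disjoint elliptic cylinders specified
  by target volume on the 0.5 × 0.5 × 5 mm grid of a proton-density scan;
  the closed-form volume is the oracle (rasterization keeps it within 2%).
  The pair generator applies fractional volume changes by scaling in-plane
  radii by $\sqrt{1+f}$ at fixed height, e.g. the −2.22% femur-scale bone
  loss a segmented bone might show.
* **Unipennate muscle** (`makePennatePhantom`): a box with line of action
  z and a constant tensor whose principal eigenvector lies at the pennation
  angle in the x–z plane; true fascicle length is the aponeurosis
  separation (box x) over $\sin\alpha$. Default eigenvalues are
  muscle-typical, $(2.1, 1.6, 1.4)\times10^{-3}$ mm²/s (MD
  $1.7\times10^{-3}$, FA 0.21) — inside the tracking FA window, unlike
  high-anisotropy nerve-like values, which would make the phantom
  untrackable under the default bounds. The default box is 10 × 20 ×
  400 mm at (1, 2, 2) mm voxels: fascicles seeded near the muscle ends
  truncate at the z faces, biasing the mean fascicle length low by roughly
  $x\cot\alpha/(3z)$, so the long box keeps that geometric artifact
  ≲3% at 15° (it is the same end-effect real muscle tractography shows at
  the tendon plate).
* **DWI simulation** (`simulateDWI`): the monoexponential single-tensor
  model at b = 500 s/mm² over 20 directions (a deterministic
  Fibonacci-sphere table, since acquisitions specify direction counts but
  schemes vary), one b = 0 volume, and optional Rician noise — Gaussian
  noise on two quadrature channels followed by the magnitude, the standard
  magnitude-MRI model.

Not emulated: realistic organ shapes, multi-compartment or non-Gaussian
diffusion, fat infiltration, partial-volume mixing at boundaries, scanner
artifacts (eddy currents, B0 inhomogeneity, motion — assumed corrected
upstream by the usual preprocessing chain). Passing the phantom suite
therefore demonstrates that the estimators are correct and stable on
well-posed geometry at realistic resolutions; it does not certify
performance on pathological or artifact-laden scans.

# Numerical choices and degenerate inputs

* Seeded operations (`seed` arguments) save and restore the caller's RNG
  state; identical seeds give bit-identical masks, signals and tract sets.
* `percentChange` requires a positive baseline; histograms require positive
  bin widths; empty masks, empty slices and empty accepted-tract sets are
  explicit errors or flags, never silent NaNs.
* Profiles that would allow non-positive thickness anywhere are rejected at
  construction.
* Tensor voxels with non-positive signal, and fits with negative
  eigenvalues beyond round-off, are flagged invalid and excluded from maps
  and tracking.
* The tracking direction at a point is the eigenvector of the containing
  voxel (nearest-neighbor); sign ties at exactly 90° flips resolve toward
  the previous direction's half-space, and the turning-angle test then
  terminates the streamline.

# Problem sizes

The shipped tests and the acceptance script run on deliberately modest
grids: fascia tubes of 10 slices at 0.3 mm (≈95×95 pixels in-plane; one
configuration at 0.15 mm), pennate boxes up to 10 × 20 × 400 mm at
(1, 2, 2) mm voxels (≈30 000 voxels), 200–1000 tracts per run. These sizes
were chosen so every closed-form comparison is well resolved while a full
validation pass remains a desk-scale computation.

# Known limitations

* Registration is integer slice alignment on one landmark; no in-plane or
  deformable registration.
* The thickness estimator inherits a sub-pixel positive bias from the
  distance transform's pixel-center sampling; at 0.3 mm pixels on a 1.2 mm
  sheet this is a few hundredths of a millimetre. Ratios (pre/post shifts)
  are less affected since the bias largely cancels.
* Tractography is deterministic single-tensor streamlining; crossing
  fibers and intramuscular fat are out of scope.
* The unipennate model ties fascicle length to one box dimension; bipennate
  or curved-aponeurosis architectures are not represented.
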