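---
title: "Methods: label-free traction force microscopy from refractive-index tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free traction force microscopy from refractive-index tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ritfm)
```

# The measurement problem

A cell adhering to a soft hydrogel pulls and pushes on its substrate. If the
gel's elasticity is known and its deformation can be measured, the surface
stress field the cell exerts — the *traction* **T**(x, y) at the gel surface
z = 0, with in-plane (shear) components T~x~, T~y~ and an out-of-plane
(normal) component T~z~ — can be recovered by inverting the elastic forward
model. `ritfm` implements this computational chain for label-free,
refractive-index (RI) tomography data: sub-resolution polystyrene beads
embedded in the gel act as fiducial markers, two volumetric images (one with
the cell exerting traction, one after the cell has been detached and the gel
has relaxed) are correlated to give the 3D displacement field **u**(**r**),
and a regularized inversion converts **u** into **T**. Because RI contrast
is also proportional to local dry-mass concentration, the same tomogram
yields the cell's dry-mass distribution, which the package converts into
surface density maps, gravitational "weight pressure", and morphology
summaries.

The package covers the computation only: phantom generation, pre-processing,
displacement estimation, the elastic model, the TV-regularized solver, and
dry-mass metrics. Optical reconstruction of the tomogram itself (field
retrieval, diffraction tomography) is out of scope; volumes enter as TIFF
stacks.

# Pipeline

The processing order is fixed: **high-pass filter → mask → global
registration → windowed correlation → traction inversion**
(`prepare_volumes()`, `estimate_displacement_field()`,
`reconstruct_traction()`, or `run_pipeline()` for the whole chain).

## High-pass filtering

Bead displacements ride on top of smooth RI variations (gel background, halo
of the cell body). `build_highpass_kernel()` constructs a zero-sum kernel on
an anisotropic support — lateral half-width w~xy~ = 0.5 µm, axial half-width
w~z~ = 1 µm by default, converted to voxels by rounding half-up — as a
fixed-width isotropic Gaussian (variance 2 voxels², the bead-scale passband)
normalized to unit sum, minus the flat mean over the support. A
Gaussian-minus-constant kernel on an anisotropic support is only
approximately zero-sum under closed-form normalization constants, so the
package renormalizes explicitly: the weights sum to zero to machine
precision for any window combination. Filtering uses reflect
padding so boundary windows are not darkened. Constant volumes map exactly to
zero; a smooth background with period ≫ window is suppressed by more than
20 dB while bead peaks stay in place
(`highpass_suppression_experiment()`).

## Masking

The cellular region itself must not contribute to gel tracking.
`apply_mask()` accepts manual rectangular boxes (`mask_box()`), axial cuts
(`mask_above_z()`), or external 8-bit TIFF masks; masked voxels are replaced
by zero or the background median, and windows whose unmasked fraction falls
below `min_valid_fraction` (default 0.5) are flagged invalid during
tracking. Automatic segmentation is deliberately out of scope.

## Global registration

Stage drift between the two acquisitions is removed by a single rigid
translation estimated from the full-volume Fourier cross-correlation with
local upsampled refinement (`global_register()`), at 1/100 voxel by default.
A normalized correlation below 0.1 is treated as non-overlapping content and
raises an error rather than returning a spurious shift.

## Displacement estimation

`estimate_displacement_field()` performs windowed digital volume
correlation: rectangular subsets (default 64³ voxels on an 11-voxel grid —
the instrument-scale settings; validation scenes in this package use smaller
subsets, see below) are compared by FFT cross-correlation, the integer peak
is refined by a matrix-multiply discrete Fourier transform on a local
upsampled grid (coarse-to-fine, factor 10 per level up to `upsample`,
default 100 = 0.01 voxel), and ties at the integer peak are broken toward
the smaller shift. Window weighting is rectangular — plain FFT correlation,
no apodization or spectral whitening. Windows that are flat, weakly
correlated (quality < 0.3), over-masked, or that report shifts larger than
half the subset are invalidated and later infilled by inverse-distance
interpolation from valid neighbours (the solver needs a complete grid);
infilled nodes stay flagged. Each recovered shift times the voxel pitch is a
displacement vector in µm at the window centre.

Two properties are worth noting. First, the recovered field is the
window-average of the continuum displacement, so spatial structure sharper
than the subset is low-pass filtered before inversion — visible in the
recovery experiments as a peak-amplitude bias. Second, the refinement
quantum (1/upsample voxel) bounds reproducibility: properties that are exact
in exact arithmetic (e.g. adding an integer shift to one volume shifts every
vector by exactly that amount) hold up to one quantum per estimate in
floating point, and the tests assert them at that tolerance.

## Elastic model

`greens_tensor()` evaluates the displacement Green's tensor of a linear
elastic half-space loaded by a point force on its free surface — the
Boussinesq solution for the normal load and the Cerruti solution for
tangential loads — at lateral offset (x, y) and depth z, with prefactor
(1 + ν)/(2πE). The implementation uses the full interior solution in
r = (x² + y² + z²)^1/2^; at the surface (z = 0, r = ρ) it reduces to the
familiar 2D traction-microscopy kernel, and for an incompressible gel
(ν = 0.5) the shear–normal coupling components vanish identically there,
with G~zz~ = 3/(4πEρ). The depth-aware form matters here because the
displacement data are measured at bead depths of one to a few µm, not at the
surface; evaluating the surface kernel at depth would make deep displacement
grow unphysically with z. A configuration flag is unnecessary — passing
`depths = 0` reproduces the surface-only evaluation.

`sample_greens_kernel()` samples all nine components on a zero-padded
lateral grid (one full domain of padding per axis, so FFT convolution equals
aperiodic summation; verified against a direct double-sum oracle at 10⁻¹⁰
relative) at each requested depth plane. The singular cell at zero offset
and zero depth is replaced by the midpoint-quadrature average of the tensor
over that grid cell (16 × 16 subgrid; the 1/ρ singularity is integrable, and
the quadrature average is accurate to better than 0.1 %); the treatment is
recorded in the kernel object. The substrate is treated as a half-space
despite finite gel thickness (tens of µm) — the standard approximation for
these geometries; finite-thickness corrections are out of scope.
`forward_displacement()` and `adjoint_displacement()` are exact transposes
of one another by construction (restriction/zero-padding and conjugate
spectra), which the dot-product test confirms to machine precision.

## Traction inversion

`reconstruct_traction()` solves

$$\arg\min_T \tfrac12 \lVert u - G\,T\rVert_2^2 + \tau \lVert \nabla T\rVert_1$$

with a monotone fast proximal-gradient method (monotone FISTA): each outer
iteration takes a gradient step on the data term and applies the total
variation proximal map, computed by fast gradient projection on the dual
(`tv_prox()`, validated against an exact non-iterative 1D TV denoiser); the
monotone variant keeps the previous iterate whenever the candidate would
increase the objective, so the objective trace is non-increasing by
construction — the guard against over-regularization artifacts at high TV
weights. TV is isotropic and acts on each traction component independently
(no cross-component coupling). The defaults are step size α = 0.01, TV
weight τ = 0.02, 200 inner (dual) and 240 outer iterations.

Two conventions make those dimensionless defaults meaningful across units
and grids. The data are normalized to unit root-mean-square, and the
operator is scaled so that the configured step size *is* the critical step
1/L of the normalized problem (L estimated by deterministic power
iteration). Without this, a fixed numeric step would be tied to one
particular unit system: with G in m/N and u in µm the raw operator norm is
~10⁻³, and α = 0.01 would advance the solve by nothing in 240 iterations.
Under this convention α controls the fraction of the critical step (1 =
maximal stable step; the safeguard warns if a configuration exceeds it) and
τ weights TV against a unit-RMS data term. The solution is rescaled to Pa
afterwards.

The inversion uses the two displacement planes nearest the gel surface
(fields with more depth planes are restricted automatically), mirroring the
practice of fitting each traction vector from two near-surface neighbouring
displacement planes; the TV term makes the solve inherently global, so the
package solves one global FFT-operator problem rather than per-node local
patches. A strict per-node local least-squares mode (`local_traction_fit()`)
is provided as an independent cross-check. Solutions are reported on the
displacement grid at z = 0, with positive T~z~ pointing from the gel into
the cell (upward).

No automatic τ selection (L-curve, GCV) is provided; τ is explicit
configuration, and the regularization-monotonicity test documents its
qualitative effect (background traction noise decreases monotonically
with τ).

## Volume deconvolution

The same monotone TV-FISTA engine drives `deconvolve_volume()`, the
constrained TV deconvolution used for RI reconstruction: a two-stage
multiscale schedule that down-samples the volume by 3, deconvolves with
α = τ = 0.003 (100 inner / 75 outer iterations), up-samples, and deconvolves
at full resolution with α = τ = 0.006 (50/25), with an optional
non-negativity constraint on the RI contrast. A delta PSF with τ = 0 returns
the input exactly; on blurred bead phantoms the round trip strictly reduces
RMSE against the ground truth.

# Synthetic data: what it emulates, and what it does not

`make_bead_phantom()` renders the fiducial-marker content of a gel tomogram:
bead count Poisson-distributed with expectation density × physical volume
(default 3 beads/µm³, the seeding density used for these gels), positions
uniform at subvoxel resolution, each bead drawn as a separable Gaussian
whose width combines the stated optical resolution (161 nm lateral / 401 nm
axial FWHM) with the second moment of a 200-nm sphere — i.e. the
PSF-blurred image of a sub-resolution bead, not a hard sphere. The bead
contrast (RI excess of polystyrene over gel as actually imaged) is not a
tabulated quantity; it is a free parameter with a nominal default of 0.05,
and the tracking chain is insensitive to it (correlation is normalized).

`deform_phantom()` computes the continuum displacement at every voxel from
the elastic forward model and warps the relaxed volume by separable
tricubic (Catmull–Rom) interpolation with constant padding (trilinear
available as an option). The relaxed state is the *reference* — the gel
after chemical detachment of the cell — and the deformed state is the
*moving* volume, so tracking deformed-against-relaxed recovers +**u**.

What the phantoms do **not** emulate: coherent imaging artifacts (the
missing-cone elongation, speckle, halo), the cell body's RI contribution,
gel inhomogeneity, and drift between acquisitions other than a rigid
translation. Passing the recovery tests therefore demonstrates the
correctness and stability of the computational chain under the stated noise
and deformation scales — not robustness to every instrument artifact.

# Validation experiments and problem sizes

Three experiment drivers, shared verbatim by the test suite and the
acceptance script, define the package's study conditions:

* **Translation ladder** (`displacement_ladder_experiment()`): one 128³
  phantom at 0.183 µm pitch; rigid lateral translations of 0.5–3 µm in
  0.5-µm steps (the stage-translation validation design); tracking with 64³
  subsets on a 24-voxel grid (27 windows per step — a desk-scale grid; the
  instrument-scale full-frame setting yields thousands of windows per
  statistic). Accuracy (mean error) is well below 0.05 voxel and per-axis
  precision below 10 nm; the response is linear with slope 1. The 64³
  subset is required at the top of the ladder: a 3-µm shift is 16.4 voxels,
  beyond the ±half-subset range of a 32³ window.

* **Traction recovery** (`traction_recovery_experiment()`): twenty seeded
  64³ scenes alternating contractile dipoles and inward rings with
  randomized orientation — 500-Pa patches (inside the typical 100–1500 Pa
  per-cell range) of 1.2-µm width, dipole separation 5 µm, ring radius
  2.5 µm, on an 11-kPa, ν = 0.5 gel. These conditions put the peak bead
  displacement at roughly 0.1–0.2 voxel (tens of nm) at the measured depth
  planes, the regime the method operates in. Tracking uses 16³ subsets on a
  4-voxel grid restricted to the two node planes nearest the surface
  (≈1.4 and 2.1 µm depth); inversion runs at the default schedule. Median
  pattern correlation across scenes exceeds 0.9, the net in-plane force
  residual stays below 5 % of the gross force, and tracking RMSE against the
  injected continuum field stays below 0.1 voxel. The recovered peak
  amplitude is biased low (typically 0.4–0.7 of truth) by the combination of
  window averaging, measurement depth, and the TV penalty at the default τ;
  the same inversion fed the exact forward displacement at surface planes
  recovers peaks within 15 % — the bias is a property of the measurement
  geometry, not of the solver.

* **High-pass suppression** (`highpass_suppression_experiment()`): a bead
  phantom plus a cosine background whose period (32 voxels by default)
  divides the volume size so its power sits on exact frequency bins; the
  spectral oracle reports > 20 dB suppression in the low-frequency band with
  the brightest bead peak unmoved.

Problem sizes (128³ ladder, 64³ scenes, 20 scenes, 10-seed Monte-Carlo
ladders) are the package's validation choices for a single-CPU run; all
conditions that correspond to instrument-scale settings (density, pitch,
subset 64³/11 defaults, solver schedule, 0.5–3 µm ladder) are kept at those
values.

# Numerical choices and degenerate inputs

* Fourier translation treats the Nyquist bin of even axes with the cosine
  (Hermitian) convention; a half-voxel round trip is exact only for signals
  with negligible Nyquist energy, which is why the exactness test uses a
  smooth object. Volume sums (mass) are conserved exactly.
* Correlation tie-breaks: all integer peaks within a 10⁻¹² relative band of
  the maximum are collected and the smallest shift (then lexicographic
  order) wins, making flat-correlation cases deterministic.
* Flat windows (zero variance) return an invalid flag, not an exception;
  fields with fewer than four valid windows abort.
* The solver's zero-data fast path returns an exact zero traction field.
* `fista_solve()` aborts with a diagnostic on non-finite iterates rather
  than propagating NaNs.
* All generators are pure functions of (spec, seed); the RNG state of the
  caller is saved and restored around every seeded draw, and solves contain
  no randomness (power iteration starts from a fixed seeded vector), so the
  end-to-end pipeline is bit-reproducible — asserted by double-run checksum.

# Known limitations

* The half-space, small-deformation, linear-elasticity assumptions are
  inherited from the underlying model; thick-gel or nonlinear corrections
  are out of scope.
* Pure-translation windows: no affine window deformation (classic DVC shape
  functions), so displacement gradients within a subset bias the estimate
  toward the window average.
* Traction is reported on the displacement grid; no super-resolution
  resampling of the traction map is attempted.
* TIFF output is uncompressed float32 (one strip per page) with a JSON
  sidecar for the voxel pitch; readers that require tiled or compressed
  TIFF should convert externally.
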