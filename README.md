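# ritfm — refractive-index traction force microscopy in R

`ritfm` implements the computational core of label-free 3D traction force
microscopy on refractive-index (RI) tomograms. A cell adhering to a soft
polyacrylamide gel deforms it; sub-resolution polystyrene beads embedded in
the gel (≈3 per µm³) act as fiducial markers. From two volumetric images —
the gel under cell traction and the relaxed gel after chemical detachment —
the package:

1. **pre-processes** the tomograms (3D Gaussian zero-sum high-pass filter,
   cell-region masking, Fourier-based global registration at subvoxel
   precision);
2. **estimates the 3D displacement field** u(**r**) by windowed FFT
   cross-correlation (digital volume correlation) with upsampled-DFT
   subpixel refinement;
3. **inverts** u into the surface traction **T**(x, y; z = 0) — shear
   (T_x, T_y) and normal (T_z) components in Pa — by solving

   argmin_T ½‖u − G T‖₂² + τ‖∇T‖₁

   with a monotone TV-FISTA solver, where G is the Boussinesq–Cerruti
   Green's tensor of a linear elastic half-space (Young's modulus E,
   Poisson's ratio ν ≈ 0.5), with prefactor (1+ν)/(2πE) and
   G_zz = 3/(4πEρ) at the surface;
4. **quantifies dry mass** from RI contrast via the refraction increment
   α = dRI/dc = 0.185 mL/g: density volumes (g/mL), projected surface
   density maps (fg/µm²), gravitational weight pressure (P = σg, sub-mPa
   for real cells — orders of magnitude below cellular tractions),
   traction histograms, frame-to-frame differential tractions, kymographs
   and 3D morphology parameters.

The same TV-FISTA engine provides the two-stage multiscale constrained
deconvolution used for RI reconstruction (`deconvolve_volume()`). A
synthetic-data module (bead phantoms, ground-truth traction patterns,
elastic forward deformation, seeded noise) makes every stage testable
without instrument data. Everything is deterministic given a seed.

## Worked example

A seeded end-to-end round trip: a bead phantom is deformed by a known
contractile dipole (500 Pa patches, 4 µm apart) through the elastic forward
model, tracked, and inverted.

```r
library(ritfm)

spec    <- phantom_spec(volume_shape = c(48, 48, 48), voxel_pitch = 0.183,
                        seed = 7)
relaxed <- make_bead_phantom(spec)
grid    <- surface_grid(48, 48, 0.183)
truth   <- make_traction_phantom(grid, "dipole", magnitude = 500,
                                 separation = 4, width = 1)
gel      <- elastic_substrate(E = 11000, nu = 0.5)   # 11-kPa gel
deformed <- deform_phantom(relaxed, truth, gel)

cfg   <- tracking_config(subset_size = 16, grid_spacing = 4,
                         upsample = 100, z_nodes = 1:2)
field <- estimate_displacement_field(relaxed, deformed, cfg)
field
#> <displacement_field> 9 x 9 x 2 nodes, 162/162 valid
#>   max |u| = 0.009331 um

traction <- reconstruct_traction(field, gel, fista_config())
traction
#> <traction_field> 9 x 9 nodes, pitch 0.732 x 0.732 um
#>   max shear 196 Pa, max |T_z| 101 Pa

st <- traction_stats(traction)
sprintf("shear mean %.1f +/- %.1f Pa, max %.1f Pa",
        st$shear$mean, st$shear$sd, st$shear$max)
#> "shear mean 80.2 +/- 62.7 Pa, max 196.4 Pa"
```

The maximum bead displacement is ≈9 nm (0.05 voxel), comfortably above the
tracker's 0.01-voxel refinement quantum; the recovered traction pattern
correlates with the injected ground truth at 0.94 on this small scene
(window averaging and the TV penalty bias peak amplitudes low — see the
methods vignette). `run_pipeline()` chains the same stages from a YAML/list
configuration and writes fields, maps and a reproducibility manifest;
`inst/cli/ritfm` exposes each stage as a shell subcommand
(`simulate`, `highpass`, `register`, `track`, `solve-traction`,
`deconvolve`, `drymass`, `stats`, `run`).

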