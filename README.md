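# fouriertomo

Fourier-grid iterative tomographic reconstruction for R: recover a 3D
volume from a tilt series of 2D projection images acquired at arbitrary
orientations, including the limited-tilt ("missing wedge") geometries of
electron tomography where a large region of Fourier space is never measured.

**Who it is for.** Anyone reconstructing volumes from parallel-beam
projections — cryo-electron tomography of cells and organelles, STEM
tomography of materials, or methodological work on iterative reconstruction
— who wants a transparent, scriptable implementation with built-in phantoms,
cross-validated convergence metrics, and angular refinement.

## The method

1. **Oversampled Fourier gridding.** By the Fourier slice theorem, the 2D
   transform of each projection is a central plane through the object's 3D
   transform. For every voxel k of an M³ grid (M = round(N·O), oversampling
   O = 3 by default), each slice plane passing within perpendicular distance
   D < D_th (default 0.5 voxel) contributes the exact discrete Fourier sum
   of its projection at the foot of the perpendicular (u, v):

       F_obs(k) = Σ_{j : D_j < D_th} [ D_j⁻¹ / Σ D_j⁻¹ ]
                  Σ_{x,y} f_j(x, y) · exp(−2πi (x·u_j + y·v_j) / M)

   Voxels no slice passes near remain *unknown*; the conjugate-symmetric
   mate of every known voxel is filled by Hermitian completion.

2. **Iterative recovery (POCS).** Starting from the measured grid, iterate:
   inverse FFT → zero voxels outside the support and negative voxels inside
   it → forward FFT → re-impose the measured voxels. Support, positivity and
   the measured data are all convex sets, so the alternating projections
   converge. Two error metrics are logged per iteration:

       R_k    = Σ |F_obs − F′_i| / Σ |F_obs|   over enforced voxels
       R_free = same ratio over a withheld 5% of known voxels (never enforced)

   R_free is the crystallography-style overfitting guard: it should track
   R_k; a widening gap signals overfitting. An optional resolution
   extension/suppression schedule enforces only low-frequency data early,
   ramps to full resolution at mid-run, then ramps back down — useful with
   noisy data.

3. **Angular refinement by projection matching.** Measured tilt angles carry
   errors; the refiner re-projects the current reconstruction over a grid of
   candidate Euler triples around each projection's estimate (±3° in 0.2°
   steps by default), scores each candidate against the measured image
   (normalized cross-correlation with free translational search, or a
   real-space R-factor), and iterates reconstruct → rescan until the
   assignment stabilizes.

Euler angles are intrinsic Z-Y-Z, degrees, acting on column vectors; a
single-axis tilt series is `(0, θ, 0)`. MRC2014 is the volume/stack format
(fast axis = x/columns, sections = z); angles are whitespace-separated
`phi theta psi` text rows (a single column is read as θ).

## Worked example

Simulate a 71-projection tilt series of a synthetic vesicle over the
±70.1° range, reconstruct it, and measure fidelity:

```r
library(fouriertomo)

phantom <- make_phantom(32, "vesicle", seed = 7)
series  <- simulate_tilt_series(phantom, seq(-70.1, 70.1, length.out = 71))
grid    <- assemble_grid(series, gridding_params(oversampling = 3,
                                                 distance_threshold = 0.5,
                                                 withheld_fraction = 0.05,
                                                 seed = 1))
grid
recon <- reconstruct(grid, params = reconstruction_params(iterations = 100))
recon
curve <- fsc(recon$volume, phantom)
round(curve$correlation[curve$shell_center < 0.5], 3)
```

```
fourier grid: M = 96 (N = 32, oversampling = 3)
  known voxels: 327993 (37.07% of grid), withheld: 16400
reconstruction: 32^3 volume (grid 96^3), 100 iterations
  R_k: final 0.0248, best 0.0248 at iteration 100
  R_free: final 0.0267
[1] 1.000 1.000 0.997 0.993 0.989 0.989 0.947 0.977
```

Reading the output: 71 slices determine ~37% of the oversampled grid; the
iteration drives the mismatch on enforced voxels (R_k) to ~2.5%, and the
withheld voxels — never used by the solver — agree almost as well
(R_free ≈ R_k), so the unknown-voxel recovery is not overfitting. The
Fourier shell correlation against the ground-truth phantom stays ≥ 0.94 in
every shell below half the Nyquist frequency despite the ±70.1° missing
wedge.

The same pipeline is scriptable from a shell (see `exec/fouriertomo`):

```sh
fouriertomo phantom     --kind vesicle --size 64 --seed 7 --output model.mrc
fouriertomo project     --volume model.mrc --angles angles.txt --output proj.mrc
fouriertomo reconstruct --projections proj.mrc --angles angles.txt \
                        --oversampling 3 --dthresh 0.5 --iterations 100 \
                        --output recon.mrc
fouriertomo refine      --projections proj.mrc --angles angles.txt \
                        --range 3 --step 0.2 --metric xcorr --outer 5 \
                        --output refined.txt
fouriertomo fsc         --a recon.mrc --b model.mrc --output fsc.csv
```

See `vignettes/fourier-grid-tomography.Rmd` for the full account of the
model, the parameter defaults, and the numerical design choices.

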