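---
title: "Fourier-grid iterative tomography: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier-grid iterative tomography: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The reconstruction problem

A tomographic tilt series is a set of $J$ parallel-beam projection images
$f^j_{\mathrm{obs}}(x, y)$ of one 3D object, each acquired at an orientation
described by a Z-Y-Z Euler triple $(\varphi_j, \theta_j, \psi_j)$. By the
Fourier slice theorem, the 2D transform of each projection equals a central
planar slice through the object's 3D transform. A limited tilt range (e.g.
$\pm 70^\circ$) leaves a wedge-shaped region of Fourier space unmeasured
(the *missing wedge*), and dose constraints limit $J$, so the measured data
cover only a small fraction of Fourier space. `fouriertomo` reconstructs the
volume by (1) assembling the measured slices onto an oversampled Cartesian
Fourier grid and (2) alternating projections between real-space constraints
(support, positivity) and the reciprocal-space measured-data constraint.
All three constraint sets are convex, so the iteration is a
projections-onto-convex-sets (POCS) scheme and converges monotonically in
the data-mismatch sense; the `rk_history` of every noise-free phantom run in
the test suite is checked for this.

## Assembling the oversampled Fourier grid

Each projection is notionally zero-padded by the linear oversampling ratio
$O$ (default 3), so the grid has side $M = \mathrm{round}(N O)$ voxels for
$N \times N$ images. For a grid voxel $\vec{k}$ (in voxel units, relative to
the DC voxel at index $\lfloor M/2 \rfloor + 1$), every slice plane $j$
passing within perpendicular distance $D_j < D_{th}$ (default 0.5 voxel)
contributes the value of the projection transform at the foot of the
perpendicular $(u_j, v_j)$:

$$
F_{\mathrm{obs}}(\vec{k}) \;=\; \sum_{\{j \,|\, D_j < D_{th}\}}
\frac{D_j^{-1}}{\sum_j D_j^{-1}}
\sum_{x,y=-N/2}^{N/2-1} f^j_{\mathrm{obs}}(x,y)\,
e^{-2\pi i (x u_j + y v_j)/M}.
$$

The inner double sum is evaluated *exactly* (a discrete Fourier sum at the
non-integer coordinates, vectorized as two complex matrix products), which
is the accurate default (`mode = "dft"`). A faster scatter variant
(`mode = "fft"`) computes one $M$-point zero-padded FFT per slice and
accumulates each slice sample onto its nearest grid voxel under the same
distance threshold and weighting; the test suite bounds its deviation from
DFT mode.

Numerical choices:

* **Exponent denominator.** The padded transform is sampled at spacing
  $1/M$ with $M = \mathrm{round}(NO)$, so integer $(u, v)$ coincide exactly
  with bins of the $M$-point zero-padded FFT (identical to $NO$ for the
  integer default $O = 3$).
* **Exact hits.** The $D^{-1}$ weight diverges as $D \to 0$. A slice with
  $D < 10^{-10}$ is an exact sample: it takes over with weight 1, ties among
  exact hits are averaged equally. This is the continuous limit of the
  weighting.
* **Hermitian completion.** Projections are real, so the object transform
  obeys $F(-\vec{k}) = \overline{F(\vec{k})}$ (mod-$M$ frequency pairing).
  After assembly, an unknown voxel whose mate is known is filled with the
  conjugate; doubly-known pairs are averaged to exact conjugate symmetry.
  This doubles effective coverage and makes the inverse transform of the
  iterate real up to rounding.
* **Nyquist sphere.** Voxels outside the inscribed radius-$M/2$ sphere are
  never marked known: corners beyond Nyquist have no measured support.
* **Interpolation error.** Inverse-distance gridding carries a first-order
  error of order $D \cdot \partial F/\partial n$. With off-center features
  the per-voxel relative error at $D \le 0.5$ oversampled voxels is a few
  percent at mid/high frequencies (and $\lesssim 1$–2% at low frequencies);
  the property tests assert these achievable bounds. $D_{th} \ge 1$ voxel
  degrades accuracy visibly and triggers a warning.

A small fraction of known voxels (default `withheld_fraction = 0.05`,
stratified by resolution shell, Hermitian pairs kept together) is withheld
from enforcement and used only for cross-validation. Five percent balances
the stability of the free R-factor against the loss of measured data.

## The iterative solver

Each iteration: inverse FFT of the Fourier iterate; take the real part
(the Hermitian-completed grid makes the imaginary part negligible, and the
object is real by assumption); zero the voxels outside the support $S$ and
the negative voxels inside it; forward FFT; log the two R-factors; then
re-impose the measured values on the enforced voxels. The R-factors are

$$
R_k = \frac{\sum_{\vec k \in \mathrm{enforced}} |F_{\mathrm{obs}} - F'_i|}
           {\sum_{\vec k \in \mathrm{enforced}} |F_{\mathrm{obs}}|},
\qquad
R_{\mathrm{free}} = \frac{\sum_{\vec k \in \mathrm{withheld}} |F_{\mathrm{obs}} - F'_i|}
                         {\sum_{\vec k \in \mathrm{withheld}} |F_{\mathrm{obs}}|},
$$

evaluated on $F'_i$, the transform of the real-space-constrained iterate,
which measures true data mismatch (the pre-constraint iterate would report
zero mismatch on enforced voxels by construction). The enforced set is
known-minus-withheld, so $R_k$ and $R_{\mathrm{free}}$ are disjoint in the
crystallographic sense: withheld voxels never influence the iterate, and a
widening gap between the two flags overfitting.

Choices a user should know:

* **Support.** Default is the centered $N^3$ cube ("loose support"): it
  separates the object region from the oversampling zero padding. A tighter
  mask strengthens the constraint and improves missing-wedge recovery.
* **Initialization.** `zeros` (deterministic default) or `random` (seeded);
  the algorithm is insensitive to the start.
* **Returned iterate.** The real-space-constrained volume at the iteration
  with minimal $R_k$, cropped to the central $N^3$. With the resolution
  schedule the final iterations enforce reduced data, so the last iterate is
  not necessarily the best-fitting one.
* **Iterations.** Fixed count, no early stopping; default 100. The
  noise-free protocol tests use 250.
* **Degenerate input.** An all-zero measured grid has a zero R-factor
  denominator; a zero mismatch is then reported as $R_k = 0$ (perfect fit)
  rather than an undefined value.

### Resolution extension/suppression

With noisy data the signal-to-noise ratio falls with spatial frequency. The
optional schedule enforces only the lowest-frequency measured data at the
first iteration, ramps the enforced radius up to full resolution in
`schedule_steps` (default 20) piecewise-constant levels over the first half
of the run, then mirrors back down (`cutoff(i) = cutoff(total - 1 - i)` up
to step quantization). Radial bands are hard cutoffs on voxel-center
distance from DC: a voxel is enforced when $r \le \mathrm{cutoff} \cdot M/2$.
The number of levels and the hard band edge are our choices; the ramp shape
is quantized so that the midpoint iteration always enforces all data. For
runs shorter than twice the step count the number of levels is reduced to
$\lfloor \mathrm{total}/2 \rfloor$ so the midpoint still reaches Nyquist.

## The Fourier-slice projector

`forward_project()` pads the volume by `pad_factor` (default 2), transforms
it once, samples the central slice for the requested orientation by
trilinear interpolation, and inverse-transforms the $N \times N$ slice. The
slice lattice is filled exactly Hermitian under the mod-$N$ DFT pairing
(canonical half interpolated, mates conjugated, self-paired points forced
real), which halves the interpolation work and guarantees a real projection
image. Samples falling outside the computed padded transform are zero; at
the identity orientation every sample is an exact FFT bin, so the projection
equals the direct $z$-sum to rounding and a centered impulse projects to a
centered impulse. Every projection's pixel sum equals the volume sum (DC
conservation); the test suite asserts this along with linearity and
agreement with an independent real-space rotate-and-sum oracle. `pad_factor
= 2` trades interpolation accuracy for the speed needed inside angular
refinement; the gridding side keeps its own, independent oversampling
$O = 3$.

## Projection-matching angular refinement

Measured tilt angles carry errors from stage drift, slipping, or software.
Refinement alternates: reconstruct with the current angles (50 iterations by
default inside the loop — cheaper than a final run); for each projection
independently, scan the full Cartesian grid of candidate triples
$(\varphi_j \pm \delta\varphi, \theta_j \pm \delta\theta, \psi_j \pm
\delta\psi)$ at `step` (defaults $\pm 3^\circ$, $0.2^\circ$), re-project the
reconstruction at each candidate, and score against the measured image;
adopt the best triple (and its translational shift) per projection; rebuild;
stop when neither angles nor shifts change, or after
`max_outer_iterations` (default 5).

Two details matter for stability. First, translations are part of the
refinement state: the recovered integer shifts are applied to the
projections whenever the reconstruction is rebuilt (the solver assumes
centered images), and a translational pre-alignment pass — a scan with the
single current-angle candidate per projection — runs before the first full
angular scan, so the first search never matches against a
translation-smeared reconstruction. Scoring always uses the measured images
as given; shifts are re-estimated fresh each pass. Second, score ties: in
floating point no two candidates ever share a score exactly, yet near the
tilt axis of a single-tilt series the in-plane angles are gimbal-degenerate
($R_z(\varphi) R_z(\psi) = R_z(\varphi + \psi)$ at $\theta = 0$), so the
score surface has a flat valley in which per-candidate differences are pure
interpolation noise. Gaps below `score_tie_tolerance` (default $10^{-4}$,
the normalized-correlation deficit observed when a reconstruction is
re-projected at its own true angles with the pad-2 trilinear projector) are
therefore treated as ties and resolved geodesically; otherwise the valley is
walked randomly and the in-plane angles accumulate error instead of
refining.

Scoring uses either the zero-mean normalized cross-correlation (`xcorr`,
maximized; the translational search over all integer shifts comes for free
via the correlation theorem, and the score is invariant to global intensity
scaling) or the real-space R-factor (`rfactor`, minimized over integer
shifts within `translation_radius`). Tie-breaking is deterministic: smallest
geodesic distance to the current estimate, then first in $(\varphi, \theta,
\psi)$ lexicographic scan order. The geodesic tie-break matters in practice:
near $\theta = 0$ the in-plane angles are gimbal-degenerate
($R_z(\varphi)R_z(\psi) = R_z(\varphi + \psi)$), so distant candidate
triples can describe the same orientation.

The exhaustive scan can be trapped in local minima; no global orientation
search is attempted. Angular error is reported as the geodesic distance on
the rotation group, $\arccos((\mathrm{tr}(R_a^\top R_b) - 1)/2)$ in degrees
— the natural convention-free metric when no reference metric is specified.

## Phantoms and noise

`make_phantom()` generates three deterministic, nonnegative test objects
with all mass inside the centered $(0.8\,\mathrm{size})^3$ cube (so the
loose support holds them with margin): `vesicle` (two nested soft-edged
ellipsoidal shells, Gaussian radial profile of width 5% of the shell radius,
plus interior Gaussian blobs — a membrane-bounded organelle stand-in),
`blobs` (random Gaussian blobs with $\sigma$ between size/24 and size/16,
centers within $\pm 0.2\,\mathrm{size}$ — chosen so single-blob mass matches
the closed-form Gaussian integral within truncation error), and `dots`
(hard spheres on a jittered lattice, an atomic-resolution stand-in).

`add_noise()` defines the dimensionless `level` relative to the mean
positive pixel of the stack so settings transfer across phantoms: `gaussian`
adds zero-mean noise with SD $= \mathrm{level} \times$ mean positive pixel;
`poisson_gaussian` scales to counts so the mean positive pixel is
$1/\mathrm{level}^2$ counts, draws Poisson noise, rescales, and adds read
noise at 10% of the count-noise SD.

What the phantoms do **not** emulate: contrast transfer functions, dose
fractionation and beam-induced motion, dynamical scattering and other
nonlinear image formation, ice background, or alignment fiducials. Passing
phantom tests therefore demonstrates correctness of the reconstruction
machinery under the linear-projection model, not robustness to every
experimental artifact.

## Test problem sizes and what the tests show

The acceptance-style tests use: the noise-free protocol at $64^3$ with 71
projections over $\pm 70.1^\circ$ and 250 iterations; the schedule
comparison at $32^3$ with 41 projections, Gaussian noise level 0.1, 100
iterations, and three noise seeds; and angular refinement at $32^3$ with 41
single-tilt projections, $\pm 2^\circ$/1-pixel perturbations, and a
$\pm 3^\circ$/$0.2^\circ$ search for up to 5 outer passes. These sizes are
the package's test conditions; quality conclusions at other scales follow
the same trends but are not asserted.

Two empirical observations from those runs, both reproducible from the test
suite, delimit what the method can do:

* With **no** missing wedge ($\pm 89^\circ$ tilts, 71 projections), the
  noise-free reconstruction correlates with the model at FSC $\ge 0.99$ in
  every shell below half Nyquist: gridding, iteration, and projection are
  mutually consistent to well under a percent.
* With the $\pm 70.1^\circ$ wedge, recovery of unmeasured wedge content
  depends on the object's spectral power: where the built-in $64^3$
  vesicle's spectrum is weak (near 0.48 of Nyquist), the global FSC can dip
  to ~0.8 in an isolated shell while every other shell below half Nyquist
  stays above 0.9. This is a property of POCS wedge recovery under a loose
  support, not an implementation defect; a tighter support raises it.

## Known limitations

* Interpolation error of inverse-distance gridding is first order in the
  slice distance; it dominates the enforced-data inconsistency (final $R_k$
  of a noise-free run is ~0.02, not 0).
* The refinement scan is exhaustive within the search box and can settle in
  local minima for large initial errors; it refines, it does not globally
  orient.
* Orientation comparisons use the geodesic metric; published angular-error
  numbers computed with other normalizations are not directly comparable.
* MRC I/O covers modes 0/1/2 and writes mode 2; TIFF reading is a
  convenience path behind the optional `tiff` package.
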