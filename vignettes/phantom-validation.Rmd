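---
title: "Validating diffusion-tensor orientation mapping with structure tensors: models, parameters and design choices"
author: "MyoTensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating diffusion-tensor orientation mapping with structure tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in MyoTensor, the parameters
that matter, what the synthetic phantom does and does not emulate, and the
numerical and design decisions taken where more than one reasonable choice
existed. Everything quantitative stated here is computed by the package's
test suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The measurement problem

Cardiac DTI summarises each ~100 µm voxel by a diffusion tensor whose
eigenvectors are read as the cell long-axis (v1), sheetlet (v2) and
sheetlet-normal (v3) directions. Because a voxel averages thousands of
cells and the signal is sensitive to many non-orientational factors, these
readings need an independent reference. A micrometre-resolution
phase-contrast volume of the same tissue provides one: per-voxel intensity
gradients carry the local orientation of cell boundaries, and a structure
tensor condenses them into the same symmetric-tensor form, with the roles
of the extreme eigenvectors reversed (least variation = cell axis = v3 of
the ST).

## Structure tensor model

Six complex quadrature filters with lognormal radial profile

R(ρ) = exp(−4 ln²(ρ/ρ₀) / (B² ln 2))

and angular profile (nₖ·û)² on the hemisphere nₖ·û > 0 are applied by FFT
convolution; the tensor is assembled per voxel as
T = Σₖ ‖qₖ‖ (nₖ nₖᵀ − I/2). The filter directions are the six icosahedral
half-axes — the canonical six-direction set, which samples orientation
space isotropically; the source material does not list its directions, so
this standard set is used. The printed normalisation I/(m−1) with m = 3
differs from the classical dual-tensor constant (5/4 nₖnₖᵀ − I/4); for this
direction set the two assemblies differ only by a global scale and a
multiple of the identity, so eigenvectors and their ordering — everything
the angle maps consume — are identical. Both variants are provided
(`variant = "printed"` is the default, `"classical"` the switch).

Key parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| centre frequency ρ₀ | π/(3√2) rad/sample | scale of structure the filter responds to |
| bandwidth B | 2 octaves | radial selectivity |
| kernel size | 11³ voxels | spatial truncation of the filter |
| smoothing | 7³ Gaussian, σ = 1.5 vox | element-wise tensor averaging |
| downsampling | 28³ block means | 3.6 µm → nominal 100 µm grid |

The spatial kernels are obtained by inverse FFT on a 64³ design grid and
truncated without windowing. Truncation re-introduces a small DC response,
which would make the tensor sensitive to the local mean intensity; the
residual mean of each truncated kernel is therefore subtracted, making the
response to constant volumes exactly zero (asserted in the tests). The
smoothing σ is not stated with the 7³ support in the source conditions;
σ = (size−1)/4 = 1.5 voxels is used, and the phantom layer results are
insensitive to σ between 1.0 and 3.5.

**Boundary handling.** FFT convolutions need padding. Mirror (symmetric)
padding reflects the boundary cell layer of the phantom — a cell touching
the slab face acquires a phantom twin, doubling its apparent thickness —
which measurably biases the boundary-layer orientation estimate (the
epicardial layer mean moves ≈0.4° away from zero). Replicate
(nearest-edge) padding extends the boundary sample without creating
structure and is the default everywhere (`pad = "replicate"`); symmetric
padding remains available.

## The synthetic phantom

`buildPhantom()` rasterises a 0.9 × 0.9 × 0.1 mm transmural slab at 3.6 µm
isotropic resolution (250 × 250 × 28 voxels; the 27.78-voxel thickness is
rounded to 28, the closest an integer grid allows to the nominal 0.1 mm).
Cuboidal cells of 108 × 18 × 14 µm are stacked along the transmural (x)
axis in sheetlets three cells deep (4 µm gaps between layers, 7 µm
cleavage gaps between sheetlets, 57 µm period) and tiled in-plane with
18 µm width / 7 µm gaps (25 µm period). Intracellular voxels take
intensity 50, gaps 100; Poisson noise replaces each voxel by a draw with
its own mean.

Design choices the source conditions leave open:

- **Lattice phase.** The lattice starts flush at the epicardial face — a
  deterministic, documented convention.
- **Helix-angle ramp.** Each sheetlet s (of n = ⌈900/57⌉ = 16) has the
  constant angle HA(s) = −88° + 176°·(s+½)/n: linear in the sheetlet's
  fractional transmural position with the first/last sheetlets half a
  period inside the range ends. This convention was selected because the
  resulting voxel-averaged reference reproduces the documented
  ±77.3° end-layer values (computed: −77.50° epi / +77.26° endo);
  alternatives (centre position over the physical extent, or s/(n−1))
  miss by 2° or more on at least one end.
- **No end-gaps along the cell long axis.** Only three gap dimensions are
  specified, none along the cell length, so cells abut end-to-end;
  strand-internal boundaries along the fiber would not change the
  gradient structure the ST measures transversely.
- **Voxel averaging.** The reference orientation per coarse voxel is the
  principal eigenvector of the mean outer product (dyadic) of
  intracellular truth long-axis vectors. Orientations are axial, so
  vector averaging would cancel antiparallel members; dyadic averaging is
  the orientation-statistics standard. Intracellular-only weighting
  matches the quantity the phantom defines truth for.
- **Transmural layers.** Coarse blocks are anchored at the volume origin;
  250 = 8·28 + 26, and the trailing 26-voxel block is kept as the ninth
  layer so the endocardial layer actually touches the endocardial face
  (dropping it would place the "endo" layer at 706–806 µm, where the ramp
  is still ≈ +59°). `downsampleTensors()` drops partial blocks by default
  (block means over unequal supports are not comparable in general); the
  validation pipeline passes `partial = TRUE` deliberately.

**What the phantom does not emulate:** curved ventricular geometry,
cell-shape and orientation dispersion, vasculature, wall-thickness
variation, imaging system blur, phase-retrieval fringes and reconstruction
artefacts. Passing phantom tests therefore demonstrates correctness of the
measurement chain on coherently organised structures at realistic noise,
not robustness to biological heterogeneity — on real tissue the kernel-size
sensitivity seen below is expected to be much weaker.

## What the phantom experiment shows

`runPhantomValidation()` (defaults = the conditions above, Poisson seed 1)
yields, per 100 µm transmural layer, the ST helix angle −76.1° ± 0.4
(epicardial) to +76.0° ± 0.3 (endocardial) against the dyadic reference
−77.5°/+77.3°, with transverse angles within 0.2° of zero — the
behaviour the chain is meant to reproduce. Interior layers agree with the
reference within ≈5°: the ST weights each sheetlet by filter-response
energy (interface area) while the reference weights by intracellular
volume, so coarse voxels mixing several sheetlets show a small systematic
difference. This is a property of the estimator, not noise (it is
unchanged across seeds), and it is asserted at its measured size in the
tests (all interior voxels within 10°, >90% within 5°).

Kernel size selects which structural scale dominates the top eigenvectors:
with a 7³ kernel (centre frequency 2π/3) v1,ST aligns with the
sheet-normal and v2,ST with the sheetlet direction; with 11³ (π/(3√2))
they swap; v3,ST stays on the cell long-axis in both cases. The
experiment records this as a classification (mean |dot| against the truth
axes), not a number.

## Phase retrieval and reconstruction

Single-distance retrieval divides the corrected frame's spectrum by
1 + (λzδ/4πβ)(u² + v²) and takes (δ/2β)·ln of the result. u, v are
angular frequencies in radians per metre — the convention is pinned by an
exact (1e−10) test against a dense discrete-Fourier oracle. The filter has
unit DC gain; frames are symmetric-padded to the next power of two before
filtering (wrap-around suppression), values are floored at 1e−9 of the
frame maximum before the log, and the clipped-pixel count is reported.
The polychromatic beam is modelled as monochromatic at λ = 6.2×10⁻¹¹ m.

Filtered back-projection uses the discrete Ram–Lak kernel (h(0) = ¼,
h(odd n) = −1/(πn)²) rather than a naive frequency ramp, which removes the
DC bias of the latter; a 64² disc phantom with 180 projections
round-trips through reconstruction and re-projection with < 2.5% relative
RMSE (the test bound is 5%).

## Transmural coordinates and angles

The transmural depth solves ∇²φ = 0 on the myocardial mask with φ = 0 on
the epicardial and φ = 1 on the endocardial boundary voxels. The discrete
6-neighbour system is solved directly as a sparse linear system
(Matrix), which gives the exact discrete harmonic solution in one step;
an iterative relaxation scheme would converge to the same solution and
was not implemented. Non-mask neighbours act as zero-flux walls;
components that do not touch both boundaries are left undefined. On a
200² annulus the solution matches the closed form ln(r/b)/ln(a/b) to
< 1e−2 when a and b are taken as the mean radii of the discrete boundary
shells (the nominal radii differ from the discrete boundary by half a
voxel, which alone accounts for ≈2e−2).

Frames: radial = normalised ∇φ, longitudinal = global long axis
orthogonalised against it, circumferential completes the right-handed
triad. Angles (all folded to (−90°, 90°] — the data are axial):

- HA: atan2(l, c) of the cell vector (positive toward +longitudinal);
- TA: atan2(r, c) (positive toward +radial, i.e. outward);
- SE: atan2(l, r) of the sheet vector; SA: atan2(c, r).

A vector with no projection onto the relevant plane has an undefined
angle (NA), and undefined markers propagate — never silently zero. Sign
conventions for SE/SA are not pinned by the source material; the above
choices are documented here and the maps are sign-flip invariant by
construction.

Bland–Altman differences are wrapped to (−90°, 90°] before statistics:
+89° and −89° describe nearly identical orientations and must differ by
−2°, not 178°. With one map near zero and the other exactly zero the
difference-vs-mean scatter lies on the slope-2 line, the known artefact
of near-zero axial comparisons; the tests construct and assert it.

## Other numerical choices

- **NLLS tensor fit**: Levenberg–Marquardt (minpack.lm) on
  (s₀, six elements), initialised from the log-linear solution with
  signals floored at 1e−12 of the voxel maximum; no positivity
  constraint — negative eigenvalues are flagged, not repaired. In the
  noiseless case the initialisation already solves the consistent system,
  and the round trip is exact to 1e−8 relative error.
- **Gradient scheme**: the 30-direction table is generated by
  electrostatic-repulsion optimisation (`repulsionDirections`, BFGS on
  the antipodal Coulomb energy) and shipped as a plain-text fixture; it
  is a synthetic stand-in for an unpublished scheme.
- **Vessel segmentation**: |I| ≥ 0.006, spherical dilation of radius
  4.4 µm, 26-connected labelling, components < 6.5×10⁴ µm³ discarded. A
  dilation radius below one voxel warns and degenerates to no dilation.
- **Tractography**: midpoint RK2 with trilinear interpolation of the
  axial field (corner vectors sign-aligned to the running direction),
  step 0.25 voxels, 30° turning threshold, 0.5 mm minimum length, one
  bidirectional seed per mask voxel. The "spline filter" of the external
  tool it mimics is undocumented; a 3-point moving average is used as a
  labelled approximation and can be switched off. Halving the step
  changes circle-field radii by < 1%.
- **Determinism**: every stochastic step takes an explicit integer seed
  and restores the caller's RNG state.

## Problem sizes

The shipped experiment runs the full 250 × 250 × 28 grid (the study's own
simulation size) in well under a minute per kernel configuration; the test
suite exercises the full grid for the main and 7³ configurations and
reduced slabs (≈80³ equivalent) for plumbing tests, and the five-point
centre-frequency sweep is validated for bank construction at all sizes.

## Known limitations

- The slab phantom cannot probe frame estimation errors (its frames are
  exact); Laplace frames are validated separately on analytic geometries.
- ST-vs-truth agreement inside mixed-orientation coarse voxels is limited
  by the energy-vs-volume weighting difference described above.
- `runRealData()` applies the same stage chain to user volumes but leaves
  registration landmark selection to the caller.
- No anisotropic voxels, no GPU paths, no multi-distance holotomography,
  no probabilistic tracking.
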