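---
title: "Divergence-constrained optical-flow slice interpolation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-constrained optical-flow slice interpolation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divflow)
```

## The problem

Stereo-PIV and similar planar velocimetry techniques measure velocity
vectors `(Vx, Vy, Vz)` on a stack of parallel planes whose out-of-plane
spacing is typically an order of magnitude coarser than the in-plane
pixel pitch.  Downstream uses of the data — wall-shear estimation,
Lagrangian tracking, visualisation — want isotropic volumes, so
intermediate slices must be interpolated.  Slice-wise linear or sinc
interpolation ignores everything we know about the fluid; in particular,
for incompressible flow the velocity field is solenoidal,

$$\nabla\cdot \mathbf{V} \;=\;
\frac{\partial V_x}{\partial x} +
\frac{\partial V_y}{\partial y} +
\frac{\partial V_z}{\partial z} \;=\; 0,$$

and naive interpolation produces mid-slices that violate this badly.
`divflow` reconstructs a mid-slice by *symmetric optical flow* between
the two bracketing slices, with the flow estimation itself penalised for
producing a divergent mid-plane field.

## The model

Let `I` denote the velocity-*magnitude* image of a slice (the scalar
brightness signal the flow solver sees) and let the target plane sit
half-way between acquired slices at offsets `±Δ` in slice-index units.
A mid-plane pixel `(x, y)` is assumed to map forward to
`(x + α, y + β)` in the upper slice and backward to `(x − α, y − β)` in
the lower slice, so `(α, β)` are *half*-displacements.  First-order
expansion of this symmetric brightness-constancy relation gives the
linear constraint `Hx α + Hy β + Hz = 0` with

* `Hx = ∂I(z+Δ)/∂x + ∂I(z−Δ)/∂x`, `Hy` analogously in `y`,
* `Hz = I(z+Δ) − I(z−Δ)`.

A second linear constraint asks the *reconstructed mid-plane field* to
be divergence-free.  Linearising the mid-plane divergence in `(α, β)`,
using only quantities available on the two outer slices, yields
`Dx α + Dy β + Dz = 0` where `Dx`, `Dy` combine second and mixed
derivatives of `Vx`, `Vy` on the two slices and

$$D_z = \frac{\partial V_x^{+}}{\partial x}
      + \frac{\partial V_x^{-}}{\partial x}
      + \frac{\partial V_y^{+}}{\partial y}
      + \frac{\partial V_y^{-}}{\partial y}
      + 2\,\frac{\partial V_z}{\partial z}.$$

The full energy is the Horn–Schunck functional with the extra quadratic
penalty:

$$E(\alpha,\beta) = \iint (H_x\alpha + H_y\beta + H_z)^2
 + \gamma^2 (D_x\alpha + D_y\beta + D_z)^2
 + \lambda^2\left(\lVert\nabla\alpha\rVert^2 +
                  \lVert\nabla\beta\rVert^2\right)\,dx\,dy .$$

The Euler–Lagrange equations are solved by a Jacobi iteration of the
classical Horn–Schunck form: each sweep replaces `(α, β)` by their
3×3 neighbourhood averages (weights 1/6 edge, 1/12 diagonal) and then
applies the exact per-pixel minimiser of the local quadratic.  The
update denominator is `γ²D1 + λ²D2 ≥ λ⁴ > 0`, so the iteration is
well-defined for any `λ > 0`.  Setting `γ = 0` recovers Horn–Schunck
exactly — `divof_solve()` and `hs_solve(gradients = "symmetric")` agree
iteration-by-iteration to machine precision, which the test suite
asserts.

All six constraint grids and the twelve update coefficients depend only
on the input slices, so they are computed once before iterating; the
per-sweep cost matches plain Horn–Schunck.

### A note on the cross-coefficient

Deriving the per-pixel normal equations gives the cross-coefficient
`B1 = A2 = λ²(HxHy + γ²DxDy)`.  This grouping is forced by two
independent identities: the update denominator must equal the
determinant `γ²(HxDy − HyDx)² + λ²D2` of the 2×2 system, and the
`γ = 0` limit must reduce to Horn–Schunck.  The implementation is
validated against an independent 2×2 linear solve on random draws
(1e−8 relative agreement).

## Reconstruction and baselines

Given the flow, each component `C ∈ {Vx, Vy, Vz}` of the mid-slice is
the motion-compensated symmetric average

$$C_{mid}(x,y) = \tfrac12\left[C_{up}(x+\alpha,\,y+\beta)
 + C_{lo}(x-\alpha,\,y-\beta)\right]$$

with bilinear sampling and replicate handling out of bounds.  Zero flow
reduces this exactly to the linear baseline, and identical outer slices
are reproduced exactly by every method — two limits the tests pin down.
Components are warped directly (rather than warping the magnitude and
re-scaling); the fields are smooth at the Reynolds numbers of biomedical
flows, so bilinear sampling suffices and higher-order sampling is not
provided.

Baselines: `linear_midslice()` (elementwise average, exact for fields
linear in z), `sinc_midslice()` (truncated-sinc weights over the
nearest `taps` slices, renormalised; it reduces to linear at
`taps = 2` and pays off for signals near the Nyquist rate of the slice
sampling, while for very smooth signals plain linear interpolation can
win — raw truncated sinc is not windowed), and the Horn–Schunck
comparator, which runs through the *identical* reconstruction path and
differs from the proposed method only by `γ = 0`, so metric differences
isolate the divergence term.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 150 | weight of the divergence penalty (enters squared). 0 disables it; values ≫ 10³ let it dominate and degrade the flow. |
| `lambda` | 1 | smoothness weight (enters squared); must be > 0 for a positive update denominator. |
| `iterations` | 2000 | Jacobi sweeps; metrics stabilise after ≈ 200, so the test suite runs 200. |
| `delta` | 1 | slice half-offset in stack positions (1: neighbours; 2: next-nearest, as when reconstructing slice 3 from 1 and 5). |
| `region` | 110 | side of the centred square window for MSE/divergence summaries (the reference protocol pads slices to 128×128 and evaluates 110×110). |
| `boundary` | replicate | stencil boundary mode (`reflect` available). |

Solvers work in pixel/slice-index units; the physical spacings
`dx, dy, dz` enter only the divergence *metric*, which divides each
derivative by its physical spacing.  The `2 ∂Vz/∂z` term of `Dz` is the
unique two-slice central estimate `(Vz⁺ − Vz⁻)/Δ`, in slice-index
units — the whole point of the two-slice formulation is to avoid
needing additional planes for the z-derivative.  Whether central or
one-sided differences were intended for the in-plane derivative terms
is not derivable from the model itself; central differences are the
default because they match the symmetric setup and keep the divergence
terms unbiased, and the boundary mode is configurable.

## Evaluation metrics

`mse_region()` reports the mean squared magnitude error over the
centred window (per-component MSEs alongside).  `slice_divergence()`
evaluates the discrete continuity residual at the mid-plane, taking the
out-of-plane derivative from the *reference* outer slices so the metric
isolates the slice under test.  Because the field plotted is a
reduction choice, both the mean absolute divergence (headline) and the
sum of squares are reported.  `sweep_weights()` repeats
interpolate-and-evaluate over a `(γ, λ)` grid; its `γ = 0` row equals
the Horn–Schunck comparator by construction.

When a reference stack is the measured data themselves (the only option
for real PIV), the held-out acquired slice — noise included — is the
MSE reference.  The package's evaluation harness follows that protocol
on synthetic stacks too, for comparability.

## The synthetic data

`analytical_field()` samples the polynomial benchmark

```
Vx = 0.3 y² + 0.15 x²
Vy = 0.3 (1 − x²) y − 1 − 0.3 x y
Vz = −0.3 (1 − x²) z
```

whose divergence is identically zero: `∂Vx/∂x = 0.3x`,
`∂Vy/∂y = 0.3(1 − x²) − 0.3x`, `∂Vz/∂z = −0.3(1 − x²)` cancel exactly.
The printed form of `Vy` admits more than one grouping; the package
adopts the unique natural parse under which the field is solenoidal and
exposes the literal alternatives behind `vy_parse` for inspection (one
of them is also solenoidal, differing only by an x-dependent offset;
the other is not).  The divergence is verified *symbolically*
(`stats::D`), not merely discretely:

```{r}
g <- grid_spec(21, 21, 21)
max(abs(symbolic_divergence_grid(analytical_field(g), g)))
```

`add_gaussian_noise()` perturbs each component with independent
zero-mean Gaussian noise whose standard deviation is 10% (by default)
of that component's maximum absolute value over the volume — the
per-component reading of "10% of the maximum velocity in each velocity
field"; a global-maximum option is provided.  Noise is added to the
sampled slices.  `solenoidal_random_field()` draws a smooth random
vector potential (low-frequency sinusoidal modes, amplitudes decaying
with `|k|`) and returns its curl, so the analytic divergence is zero by
construction and the discrete central-difference divergence is `O(h²)`
— the order study in the tests observes the ≈ 4× error drop per spacing
halving on this field.  (On the polynomial benchmark the central
stencils are *exact* — every component is at most quadratic per axis —
so its discrete divergence is machine zero at any resolution, a
stronger statement the tests also assert.)  `translation_phantom()`
builds a Gaussian blob and an analytically shifted copy on the 8-bit
brightness scale, so that brightness gradients dominate `λ = 1` and
Horn–Schunck recovers the shift.

The default stack geometry mirrors the reference protocol: 7 slices of
128×128 over `[−1,1]³`, so `dz ≈ 21 dx` — the anisotropy regime the
method targets — with slices 3–5 as reconstruction targets.

### What the synthetic stacks do and do not show

The noisy analytic stack exercises every code path under controlled
conditions, but it is a *stand-in* for measured PIV: its magnitude
image is nearly z-invariant (only `Vz`, the smallest component, varies
with z), so the outer magnitude images differ essentially by noise and
the brightness term carries little true motion information.  Two
consequences, both reproduced deterministically by the suite:

* the divergence term *reduces* mid-slice divergence markedly at the
  reference weights (γ = 150 vs γ = 0), on every target slice — the
  method's central claim, which transfers;
* the MSE-versus-γ profile is *not* monotone increasing on this
  stand-in: going from γ = 0 to γ = 50 the MSE drops, because the
  divergence penalty suppresses the flow's response to noise (it acts
  as a denoiser here).  A monotone MSE increase is a property of data
  with genuine z-structure in the magnitude signal, not of the
  algorithm; passing or failing it on synthetic stacks says nothing
  about real acquisitions.

## Numerical choices

* Flow initialised to zero: deterministic, and makes "identical frames
  → zero flow" an exact fixed point.
* Fixed iteration count (no convergence test) for protocol fidelity; an
  optional `tol` enables early stop on the max per-sweep update.
* Replicate boundary for all stencils by default; `reflect` mirrors
  about the edge pixel.
* Padding (`pad_to`) centres per dimension, cropping before padding;
  placement offsets are recorded so the evaluation window can be mapped
  back.
* Degenerate inputs fail fast with descriptive errors (shape
  mismatches, non-finite values, `λ ≤ 0`, evaluation window larger than
  the slice).
* Oracle comparisons of the coupled update use draws with `λ ≥ 0.5`:
  below that, with `γ` in the thousands, the per-pixel 2×2 system's
  conditioning (`κ ∼ γ²/λ⁴`) makes 1e−8 agreement unattainable for
  *any* pair of correct implementations.

## Problem sizes used in the checks

The packaged checks run the full 128×128, 7-slice geometry with 200
iterations (where the metrics have stabilised) for the stack-level
properties, 64×64 pairs for the reduction identity, and 1000-draw
per-pixel oracles; the γ-sweep covers {0, 50, 150, 500, 2000} at λ = 1.

## Known limitations

* Dense rectangular grids only: no masks, no NaN-aware arithmetic (PIV
  regions of interest must be cropped/padded first, see `pad_to()`).
* Single-scale solver: no pyramid/warping scheme, so reliable only for
  sub-pixel to few-pixel inter-slice displacements.
* Quadratic penalties throughout; no robust (e.g. Charbonnier) variants
  or vorticity regularisers.
* The truncated-sinc baseline is unwindowed, matching its common use as
  a comparator rather than a tuned interpolator.
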