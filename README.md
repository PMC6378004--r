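# divflow

Divergence-constrained optical-flow interpolation of velocimetry slice
stacks.

## The problem

Planar velocimetry (e.g. stereo PIV) measures 3-component velocity
vectors on a stack of parallel planes whose out-of-plane spacing is far
coarser than the in-plane resolution.  Reconstructing the missing
intermediate slices by linear or sinc interpolation ignores the physics:
for incompressible flow the velocity field must be solenoidal,
`∇·V = ∂Vx/∂x + ∂Vy/∂y + ∂Vz/∂z = 0`, and naive interpolants violate
this badly.  `divflow` is for experimentalists and image analysts who
need mid-slices that are both accurate and physically consistent.

## The method

A mid-plane pixel is assumed to map symmetrically into the two
bracketing slices, `I(x+α, y+β, z+Δ) = I(x−α, y−β, z−Δ)`, where `I` is
the velocity-magnitude image and `(α, β)` the per-pixel
half-displacement field.  The flow minimises

    E = ∬ (Hx α + Hy β + Hz)²                 symmetric brightness constancy
        + γ² (Dx α + Dy β + Dz)²             linearised mid-plane divergence
        + λ² (‖∇α‖² + ‖∇β‖²) dx dy           smoothness

by a Horn–Schunck-style Jacobi iteration (3×3 neighbourhood averaging
plus an exact per-pixel 2×2 minimiser).  At `γ = 0` the solver reduces
exactly to Horn–Schunck; the divergence terms are built from the two
outer slices only, so no extra planes are needed for the z-derivative.
The mid-slice is then the motion-compensated symmetric average of each
velocity component.  Linear, truncated-sinc and Horn–Schunck baselines
share the same reconstruction path, so comparisons isolate the
divergence term.  Reference protocol defaults: `γ = 150`, `λ = 1`,
2000 iterations, 110×110 centred evaluation window.

See `vignette("divflow-methods")` for the derivation, parameter
guidance and the synthetic-data design.

## Worked example

Build the noisy anisotropic benchmark stack (7 slices of 128×128, 10%
Gaussian noise), reconstruct slices 3–5 from their neighbours with the
constrained solver, the Horn–Schunck comparator and the linear
baseline, and score them against the held-out acquired slices:

```r
library(divflow)

grid  <- grid_spec(nx = 128, ny = 128, nz = 7)
stack <- add_gaussian_noise(analytical_field(grid), fraction = 0.1, seed = 1)
cfg   <- solver_config(gamma = 150, lambda = 1, iterations = 200,
                       delta = 1, region = 110)

evaluate(stack, interpolate_volume(stack, "divof", cfg, targets = 3:5), cfg)
#> <eval_report> method = divof
#>  slice        z      mse    mse_vx   mse_vy    mse_vz div_mean_abs div_ss
#>      3 -0.33333 0.022853 0.0024924 0.023510 0.0011369       2.3783 109108
#>      4  0.00000 0.022362 0.0025286 0.022851 0.0011219       2.3702 107841
#>      5  0.33333 0.021978 0.0024795 0.022577 0.0010967       2.3484 106587
#> aggregate: mse = 0.022398, div_mean_abs = 2.3656, div_ss = 1.0785e+05

evaluate(stack, interpolate_volume(stack, "hs", cfg, targets = 3:5), cfg)
#> aggregate: mse = 0.025343, div_mean_abs = 3.2564, div_ss = 2.0155e+05

evaluate(stack, interpolate_volume(stack, "linear", cfg, targets = 3:5), cfg)
#> aggregate: mse = 0.027157, div_mean_abs = 3.638, div_ss = 2.5196e+05
```

`mse` is the mean squared error of the velocity magnitude over the
centred 110×110 window against the held-out slice; `div_mean_abs` is
the mean absolute discrete divergence of the reconstructed mid-plane
(physical spacings applied, out-of-plane derivative from the reference
outer slices).  On this stack the divergence term cuts the mid-slice
divergence by roughly a third relative to Horn–Schunck (2.37 vs 3.26)
while also improving the MSE; `sweep_weights()` maps the whole (γ, λ)
trade-off.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/divflow.R simulate --field analytic --nx 128 --ny 128 \
    --nz 7 --noise 0.1 --seed 1 --out stack.csv
Rscript inst/cli/divflow.R interpolate --in stack.csv --method divof \
    --delta 1 --targets 3,4,5 --out recon.csv
Rscript inst/cli/divflow.R evaluate --truth stack.csv --recon recon.csv \
    --region 110 --json report.json
```

Volumes are single delimited-text files with a commented header (shape,
spacings, z-coordinates) and `i,j,k,x,y,z,vx,vy,vz` rows — diffable and
close to columnar ASCII PIV exports.

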