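# dcefit

Quantitative analysis of dynamic contrast enhanced MRI (DCE-MRI) in R:
variable-flip-angle T1 relaxometry, tracer-kinetic (Tofts-Kety) model
fitting with an in-package Levenberg–Marquardt solver, and a phantom-based
validation harness built on QIBA-style digital reference objects.

## The problem

DCE-MRI acquires heavily T1-weighted images continuously while a
gadolinium contrast agent is injected. Each voxel's intensity time course
carries physiological information: the volume transfer constant
K<sup>trans</sup> (min⁻¹), the extravascular extracellular volume fraction
v<sub>e</sub>, and the plasma volume fraction v<sub>p</sub>. Estimating
these maps requires a chain of model inversions that this package
implements end to end:

1. **T1 mapping.** Multiflip spoiled gradient echo (SPGR) data follow

   S = S₀ sinθ (1 − e^(−R₁ T_R)) / (1 − cosθ e^(−R₁ T_R)),

   fitted voxelwise for R₁(x,0) and S(x,0) (DESPOT1 linearization for the
   start, Levenberg–Marquardt for the refinement). Voxels below 10% of
   the maximum mean intensity are excluded as noise-dominated.

2. **Signal inversion.** The dynamic series is converted to R₁(x,t) by
   inverting the SPGR equation on the normalized signal
   s(x,t) = S(x,t)/S(x,0), in a form with all sinθ terms eliminated
   (less sensitive to B1 inhomogeneity), then to concentration via
   C_t = (R₁(x,t) − R₁(x,0))/r₁ with relaxivity r₁ = 4.5 s⁻¹mM⁻¹ by
   default.

3. **Tracer kinetics.** The Extended Tofts-Kety model

   C_t(t) = K^trans ∫₀ᵗ C_p(s) e^(k_ep (s−t)) ds + v_p C_p(t),
   k_ep = K^trans / v_e,

   with the Standard model (v_p = 0) and a plasma-only model
   (K^trans = 0) as special cases, selectable by bitmask (1/2/4) and
   compared per voxel by reduced χ². Fitting runs in (K^trans, k_ep, v_p)
   space, which conditions better than fitting v_e directly; the
   convolution uses an exact composite-trapezoid recursion and analytic
   Jacobians. Voxels are masked automatically by signal enhancement ratio
   (SER > 2.0) unless a mask is supplied; fitted v_e, v_p are clamped to
   [0, 1] and K^trans to [0, 5] min⁻¹ afterwards.

All fitting code is in-package; no external optimizer is called.
Voxelwise fitting parallelizes over deterministic index blocks, so
results are bit-identical for any worker count.

## Worked example

Generate the standard-layout digital reference phantom (the 6 × 5 grid of
K^trans ∈ {0.01, 0.02, 0.05, 0.1, 0.2, 0.35} min⁻¹ and
v_e ∈ {0.01, 0.05, 0.1, 0.2, 0.5}, 10 × 10 voxel patches over a vessel
strip), then run the whole pipeline against it:

```r
library(dcefit)
ph <- generate_phantom(phantom_spec("standard"))
report <- run_validation(ph)
report
#> <dce_validation_report> standard layout; 30 voxels; sigma = 0
#> # A tibble: 2 × 5
#>   parameter rms_pct max_pct   ccc     n
#>   <chr>       <dbl>   <dbl> <dbl> <int>
#> 1 ktrans      0.524    2.33 1.000    30
#> 2 ve          0.492    2.15 1.000    30
```

Reading: fitting one voxel per homogeneous region, the recovered
K^trans values agree with the imposed truth to 0.52% RMS (worst region
2.3%), v_e to 0.49% RMS, and Lin's concordance correlation coefficient
exceeds 0.999 for both — near-perfect noise-free recovery, with the
largest deviations confined to the ill-conditioned v_e = 0.01 column.
`autoplot(report)` draws the per-region error map;
`tidy(report)`/`glance(report)` return the metrics and run metadata as
tibbles.

The same driver accepts Rician noise
(`run_validation(ph, noise = noise_spec(0.2, seed = 1))`, which keeps all
100 voxels per region) and DICOM phantom directories
(`load_qiba_phantom("path/to/dicom", layout = "standard")`).

## Command line

```sh
inst/scripts/dcefit input.mat --models 6 --workers 4
inst/scripts/dcefit --validate --phantom synthetic --layout extended
```

The MAT v5 contract: inputs `t` (s), `Cp` (mM), `DCEdata` (time-first
array), and either `R10`/`S0` maps or `T1data`/`T1flip`; optional `mask`,
`models`, `relaxivity`, `TR`, `outfile`. Outputs `Ktrans`, `kep`, `ve`,
`vp`, `resid`, `modelmap`, `R10`, `S0`, `SER`, `mask`.

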