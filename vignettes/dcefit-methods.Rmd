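---
title: "Models, numerics and validation design in dcefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and validation design in dcefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcefit)
```

This vignette is the package's own account of the science it implements:
the signal and tracer-kinetic models, the numerical choices behind them,
what the synthetic digital reference phantoms emulate, and the known
limits of what a passing validation shows.

## Signal model and relaxometry

The spoiled gradient echo (SPGR) steady-state signal is

$$S = S_0 \sin\theta\,\frac{1 - E_1}{1 - \cos\theta\,E_1},
\qquad E_1 = e^{-R_1 T_R},$$

with flip angle $\theta$ (degrees at every public boundary, converted
once internally), repetition time $T_R$ in seconds, and longitudinal
relaxation rate $R_1$ in s$^{-1}$. $R_2^*$ decay is neglected, which
assumes $T_E \ll 1/R_2^*$; the echo time is carried for information
only.

**Multiflip fitting.** `fit_r1_maps()` estimates $(S_0, R_1)$ per voxel
from variable flip angle data. The start comes from the DESPOT1
linearization — regressing $S/\sin\theta$ on $S/\tan\theta$ gives slope
$E_1$ and intercept $S_0(1-E_1)$ — which is exact for noise-free data,
so the subsequent Levenberg–Marquardt refinement matters only under
noise. The regression slope is clamped into $(0,1)$ before the logarithm
so that noisy voxels yield finite rates rather than errors. Voxels whose
mean multiflip intensity falls below a configurable fraction (default
0.10) of the global maximum are excluded as noise-dominated and carry a
zero sentinel in the returned maps.

**Dynamic inversion.** `invert_spgr()` inverts the signal equation on
the normalized signal $s(x,t) = S(x,t)/S(x,0)$ in the
$\sin\theta$-free form

$$R_1(x,t) = -\frac{1}{T_R}\log
\frac{1 - s + s\,E_{10} - E_{10}\cos\theta}
     {1 - s\cos\theta + s\,E_{10}\cos\theta - E_{10}\cos\theta},$$

where $E_{10} = e^{-R_1(x,0)T_R}$. Eliminating $\sin\theta$ matters
because its relative error near small flip angles exceeds that of
$\cos\theta$, so this form is less sensitive to transmit-field (B1)
inhomogeneity. Where noise drives the log argument non-positive the
sample becomes a counted NaN sentinel rather than an error: isolated bad
voxels must not abort a whole-volume run. Normalization uses the
supplied $S_0$ map when present, otherwise the mean of the first three
pre-contrast dynamics rescaled through the forward model at $R_1(x,0)$
(three baseline frames are required anyway by the enhancement-ratio
mask). Spatially varying flip angles are out of scope; if a B1 map is
available it should be used upstream to produce an $R_1$ map that is
then supplied directly.

Concentration follows as $C_t = (R_1(x,t) - R_1(x,0))/r_1$ with the
relaxivity $r_1$ defaulting to 4.5 s$^{-1}$mM$^{-1}$ (Gd-DTPA at 3 T).
Negative concentrations are preserved — they are informative noise, and
clamping happens only on fitted parameters.

## Tracer-kinetic models

The Extended Tofts-Kety model treats the voxel as a plasma compartment
exchanging with an extravascular extracellular space:

$$C_t(t) = K^{\mathrm{trans}} \int_0^t C_p(s)\,
e^{k_{ep}(s - t)}\,ds + v_p\,C_p(t),
\qquad k_{ep} \equiv K^{\mathrm{trans}}/v_e.$$

The Standard model sets $v_p = 0$; the plasma-only (no-exchange) model
sets $K^{\mathrm{trans}} = 0$. Models are chosen by bitmask (1
plasma-only, 2 standard, 4 extended, OR-combinable); when several are
fitted, the per-voxel winner minimizes the reduced $\chi^2 =
\mathrm{SSR}/(N - p)$, with ties broken toward fewer parameters. Unit
noise variance is assumed in $\chi^2_{red}$ — no per-voxel $\sigma$ is
estimated — which is valid for comparing models at a fixed voxel because
the unknown variance scales all candidates equally.

**Parameterization.** Fits run in $(K^{\mathrm{trans}}, k_{ep}, v_p)$
space and derive $v_e = K^{\mathrm{trans}}/k_{ep}$ afterwards, guarding
$k_{ep} = 0 \mapsto v_e = 0$ (no measurable efflux means no estimable
$v_e$). Fitting $k_{ep}$ instead of $v_e$ conditions better: the
$v_e$-parameterized Jacobian columns

$$\frac{\partial C_t}{\partial K^{\mathrm{trans}}} =
\int_0^t C_p\,e^{k_{ep}(s-t)}\Big[1 + \frac{K^{\mathrm{trans}}}{v_e}(s-t)\Big] ds,
\qquad
\frac{\partial C_t}{\partial v_e} =
-\frac{(K^{\mathrm{trans}})^2}{v_e^2}\int_0^t C_p\,e^{k_{ep}(s-t)}(s-t)\,ds$$

both depend on $K^{\mathrm{trans}}$ in similar ways and degenerate as
$v_e \to 0$. Both parameterizations are implemented (the
$v_e$ form is retained for conditioning analysis); unit tests verify
each against central finite differences, and a property test asserts
that the standard-model Jacobian's condition number at $v_e = 0.01$
exceeds that at $v_e = 0.5$.

**Quadrature.** The convolution integral is evaluated by the composite
trapezoidal rule on the acquisition grid, which may be non-uniform. It
is computed through the interval recursion

$$K_i = e^{-k_{ep}\Delta_i} K_{i-1} +
\tfrac{\Delta_i}{2}\big(C_{p,i-1} e^{-k_{ep}\Delta_i} + C_{p,i}\big),$$

which is algebraically identical to the direct double-loop trapezoid sum
(the exponential kernel factorizes across intervals; a unit test asserts
bit-level agreement with the direct form) but costs $O(N)$ per curve and,
more importantly, never evaluates $e^{+k_{ep}s}$: at the grid corner
$k_{ep} = 35$ min$^{-1}$ over an 11-minute window the naive factored
form overflows double precision. The same recursion yields the
$\partial/\partial k_{ep}$ integral for the Jacobian. Tissue curve and
AIF must share one time grid; no interpolation is attempted, and the
trapezoid error is second order (halving the step reduces error at least
3.5-fold in the order test).

## The Levenberg–Marquardt solver

All fitting uses the in-package `levmar()`: damped normal equations
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = -J^\top r$,
$\lambda$ multiplied by 10 on rejection and divided by 10 on acceptance,
so accepted steps never increase the cost. Defaults: $\lambda_0 =
10^{-3}$, gradient/step/cost tolerances $10^{-8}$, 200 iterations;
hitting the iteration cap returns the best parameters seen with
`converged = FALSE`. These hyperparameters are this package's choices,
stated rather than inherited. The solver is unconstrained; physiological
clamping ($v_e, v_p \in [0,1]$, $K^{\mathrm{trans}} \in [0,5]$
min$^{-1}$) is applied afterwards, and pre-clamp residuals are kept so
that poorly fitted voxels remain identifiable. Residual-based filtering
is deliberately left to the user: the correct cutoff is data-dependent,
so the package exposes residual maps and nothing more.

DCE fits start from $K^{\mathrm{trans}} = 0.1$ min$^{-1}$, $k_{ep} =
0.5$ min$^{-1}$, $v_p = 0.01$ — mid-range of the phantom grids;
noise-free tests confirm the solution is insensitive to this choice. T1
fits start from the DESPOT1 estimate.

**Determinism and parallelism.** `fit_voxels_parallel()` splits voxels
into contiguous index blocks, fits each block in a forked worker, and
reassembles by index. Because chunk boundaries never change the
arithmetic of any single-voxel fit, results are bit-identical for every
worker count — a standing regression test, and the property that makes
validation reports reproducible.

## Masking and postprocessing

The signal enhancement ratio is the mean of the last three dynamics over
the mean of the first three, per voxel; the automatic processing mask
keeps voxels with SER strictly above 2.0 (a voxel at exactly 2.0 is
excluded — the threshold is "above"). A zero pre-contrast baseline gives
SER 0 with a flag. Both the cutoff and the pre/post window are
configurable, and a user-supplied mask bypasses SER entirely.

## The synthetic digital reference phantoms

`generate_phantom()` builds a phantom with the QIBA Tofts-Kety layouts:

* standard: $K^{\mathrm{trans}} \in \{0.01, 0.02, 0.05, 0.1, 0.2,
  0.35\}$ min$^{-1}$ $\times$ $v_e \in \{0.01, 0.05, 0.1, 0.2, 0.5\}$,
  30 regions;
* extended: $K^{\mathrm{trans}} \in \{0, 0.01, 0.02, 0.05, 0.1, 0.2\}$
  $\times$ $v_e \in \{0.1, 0.2, 0.5\}$ $\times$ $v_p \in \{0.001, 0.005,
  0.01, 0.02, 0.05, 0.1\}$, 108 regions;

each region a homogeneous 10 × 10 voxel patch, with a vessel strip along
the bottom carrying the AIF signal, from which `extract_aif()` recovers
$C_p(t)$ by the same inversion chain used for tissue.

Choices a real phantom would fix but the generator must:

* **Acquisition constants** (TR 5 ms, flip 30°, 661 frames at 0.5 s,
  tissue $R_{10} = 1.0$, blood $R_{10} = 1/1.4$ s$^{-1}$) are
  configuration, typical of short-TR dynamic protocols; DICOM headers
  override them when a real phantom is loaded.
* **AIF**: a parametric population curve — biexponential washout
  (amplitudes 3.99 and 4.78 mM, rates 0.144 and 0.0111 min$^{-1}$,
  overall scale 0.75) modulated by a smooth bolus arrival
  $(1 - e^{-12\tau})$ at $t_0 = 30$ s — peaking near 6 mM, the familiar
  shape and magnitude of a gadolinium bolus. It plays the role of a
  population AIF without claiming any specific published phantom's exact
  curve.
* **Amplitude and quantization**: signals are scaled ($S_0 = 50000$, a
  16-bit-style intensity range giving a tissue baseline near 900 counts)
  and rounded to integers, as any DICOM-delivered reference object is.
  Quantization is what gives the noise-free validation a realistic error
  floor; without it the fits recover the truth to machine precision and
  say nothing about conditioning.
* **Forward integration** runs on a 10× refined time grid and samples at
  the acquisition times. Generating and fitting on the same grid with
  the same quadrature would make the fit an inverse crime; the
  oversampling keeps the generated data slightly — and realistically —
  inconsistent with the fitting quadrature.
* **Noise**: `add_rician_noise()` adds complex Gaussian noise of
  standard deviation $\sigma_{rel}$ relative to the pre-contrast
  baseline to both channels and takes the magnitude, producing Rician
  statistics (Rayleigh in zero-signal voxels — the mean check
  $\sigma\sqrt{\pi/2}$ is a unit test). "Baseline" is the global mean
  pre-contrast tissue signal, a definition chosen once and configurable;
  the vessel strip is left noise-free by default so the AIF stays exact.
  Noise is seeded and the caller's RNG state is preserved.

## Validation protocol and what it shows

`run_validation()` executes AIF extraction → inversion → concentration →
fitting → clamping → metrics. Noise-free runs analyse one voxel per
region (all voxels in a region are identical — a property under test);
noisy runs keep all 100 to sample the noise distribution. Extended-model
runs drop the $K^{\mathrm{trans}} = 0$ regions first: without transfer
the two-compartment assumptions fail and $v_e$ is not estimable, leaving
90 regions. Metrics per parameter are RMS percent error
($100\sqrt{\mathrm{mean}((\hat x - x)/x)^2}$ — interpreted as the RMS of
per-voxel relative errors, consistent with reporting a percent
"maximum error"), maximum percent error, and Lin's concordance
correlation coefficient with population moments. Zero-truth entries are
the caller's responsibility to exclude, and the only exclusion applied
is the stated $K^{\mathrm{trans}} = 0$ removal — no outlier trimming.

On the default phantoms the noise-free standard run recovers
$K^{\mathrm{trans}}$ to about 0.5% RMS and $v_e$ to about 0.5% RMS with
CCC > 0.999, the worst regions lying in the $v_e = 0.01$ column; the
extended run has CCC > 0.999 for $K^{\mathrm{trans}}$ with its worst
regions at $K^{\mathrm{trans}} = 0.01$ (largest at $v_e = 0.5$, i.e.
smallest $k_{ep}$). Both structures are the conditioning signature
discussed above, emerging from quantization-level perturbation — they
are computed by `scripts/acceptance.R` and asserted in the test suite,
not assumed.

**What passing does not show.** The synthetic phantom is homogeneous,
motion-free, noise-free in its AIF, and driven by a smooth population
bolus; real acquisitions violate all four. Under $\sigma = 0.2$ Rician
noise a minority of voxels in ill-conditioned corners (lowest $v_e$,
where $k_{ep}$ reaches 35 min$^{-1}$) run away along the flat
$(K^{\mathrm{trans}}, k_{ep})$ valley to the clamp bound; because
relative errors divide by small truths, these dominate RMS and depress
per-voxel CCC even though median recovery stays accurate (the median
fitted $K^{\mathrm{trans}}$ at truth 0.01 min$^{-1}$ is 0.0099 in the
seeded run). Published noisy-phantom accuracies obtained on specific
reference objects depend on those objects' AIF heat and signal scale and
are not directly comparable to the synthetic numbers; the package
asserts the robust qualitative facts instead (noise degrades RMS by far
more than an order of magnitude; low-signal corners fail first).
In vivo, voxels violating the compartment assumptions (necrosis, partial
volume with vessels) produce large residuals rather than diagnostics —
hence the retained residual maps.

## Problem sizes

The default test suite runs entirely on generated data: full-size
phantoms (70 × 50 and 190 × 60 voxels, 661 frames) for the end-to-end
checks, reduced grids (2 × 2 patches, 151–201 frames) for module-level
tests, and $10^5$-draw noise checks — a few tens of seconds in total.
The acceptance script adds the $\sigma = 0.2$ standard run over all
3000 region voxels, completing in well under a minute on one core.
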