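---
title: "Methods: simulating and reconstructing HDR source positions with a couch-embedded diode array"
author: "mplocate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing HDR source positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplocate)
```

## The verification problem

High-dose-rate (HDR) prostate brachytherapy steps a high-activity Ir-192
source through implanted catheters. A flat 11 × 11 diode array embedded in
the treatment couch beneath the patient can, in principle, verify every
dwell position in real time: each diode's absorbed dose is a monotone
function of its distance to the source, so the dwell position is the point
whose distances to the diodes best explain the measured dose pattern.
`mplocate` simulates this chain end to end and quantifies how the
reconstruction degrades with patient tissue heterogeneity and with the
number of detectors used — and how CT density information restores it.

The coordinate frame is right-handed with the origin at the array's corner
diode: x runs patient left–right, y superior–inferior (the catheter
direction), and z anterior–posterior, with the array in the z = 0 plane
and its normal pointing up (+z) into the patient.

## Forward model

### TG-43 line-source dose

The analytic dose model is the AAPM TG-43U1 factorization for a line
source of active length L = 3.5 mm:

$$\dot D(r,\theta) \;\propto\;
\frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\; g_L(r)\; F(r,\theta),$$

with the geometry function $G_L = \beta/(L r \sin\theta)$ (where $\beta$
is the angle the active segment subtends at the field point), reducing to
$1/(r^2 - L^2/4)$ on the long axis and to the point-source $1/r^2$ for
$r \gg L$. The reference point is $r_0 = 10$ mm, $\theta_0 = 90^\circ$.
Interfaces take millimetres and degrees; the geometry function is
evaluated in centimetres internally and reported in cm⁻².

The radial dose function and anisotropy tables shipped with the package
are **synthetic stand-ins**, not published consensus data: the pipeline is
self-consistent (the same model is used forward and inverse), so only the
qualitative shape matters — near-unity $g_L$ over 1–100 mm with slow
falloff, and an anisotropy dip toward the source poles. The g-table knots
were generated from a smooth fifth-order polynomial with that shape, and
the default fit is a fifth-order polynomial renormalized to
$g_L(10\,\mathrm{mm}) = 1$ exactly (a shape-preserving monotone cubic
interpolant is available via `method = "interp"`). Users with consensus
tables can load them from two/three-column text files; all conclusions
about *relative* accuracy are insensitive to this substitution, but
absolute dose maps are not meaningful.

### Heterogeneity as attenuation scaling

The gold standard for dose in a heterogeneous patient is Monte Carlo
photon transport in the voxelized CT geometry. This package instead
perturbs the TG-43 water dose by primary-photon attenuation along the
source–detector ray:

$$D = D_{\mathrm{TG43}}(r,\theta)\,
\exp\!\big(-\mu_{\mathrm{eff}}\,(\mathrm{WEPL}-r)\big)
\cdot A(\varphi),$$

where WEPL is the water-equivalent path length through the density grid
(exact Siddon voxel traversal, ray segments outside the grid counted at
water density 0.998 g/cm³), $\mu_{\mathrm{eff}} = 0.111$ cm⁻¹ is the
linear attenuation coefficient of water near the ~0.38 MeV mean Ir-192
photon energy, and $A(\varphi)$ is the detector's directional response
(unity by default; a cos^p model is available to exercise the angular
correction). This is an openly declared model substitution: it reproduces
the *direction* and rough magnitude of the heterogeneity effect — excess
attenuation in tissue, bone and the carbon couch depresses doses, which
the inversion reads as extra distance — without transporting secondaries.
Attenuation uses voxel density only (Compton dominance makes
electron-density scaling a reasonable first-order model); material labels
are retained for reporting. Scatter build-up, beam hardening and the
changing primary-to-scatter ratio are *not* modelled, so passing tests
demonstrate internal consistency and the correct physics direction, not
Monte Carlo fidelity.

### Synthetic study geometry

No patient CT is shipped. `make_pelvic_phantom()` builds a pelvic-like
stand-in on a 3 mm voxel grid (48 × 48 × 40 by default): an elliptical
soft-tissue body (1.00–1.06 g/cm³ with seeded uniform jitter) resting on a
carbon couch slab (1.7 g/cm³) whose anterior surface sits 5 mm above the
detector plane, two femoral-head-like bone ellipsoids (1.85 g/cm³), an
optional rectal gas pocket (0.0012 g/cm³), and air elsewhere. The
HU→density curve and density→material bins are standard-shaped defaults
standing in for a scanner-specific calibration; both are replaceable. `override_to_water()` reproduces the water-override
experiment: same grid, every voxel at 0.998 g/cm³.

`make_dwell_plan()` emulates the treated plan: 4 catheters along y placed
at the corners of a 40 mm lateral × 30 mm height extent (30–70 mm in x,
30–60 mm in z above the array, spanning the minimum and maximum
clinically plausible source-to-array distances for a prostate implant),
3 consecutive dwells per catheter at exactly 3 mm steps — 12 dwell
positions. The 10 mm diode pitch is adopted from the array's design
literature and is configurable.

Measurement noise is multiplicative Gaussian, $N(1, \sigma^2)$ with
$\sigma = 1\%$ by default (a realistic k = 1 repeat-to-repeat spread for
this measurement), applied independently per reading; the
calibration dose $D_{10}$ — a single detector at 10 mm on the transverse
axis in water, which equals the model's strength scale by construction —
is noiseless.

## Reconstruction

1. **Normalization**: $\alpha_i = D_i / D_{10}$ for the selected
   detectors (the n highest-dose detectors, n ∈ {9, 25, 49, 81, 121},
   ties broken by detector index).
2. **Inversion**: $r_i = \alpha^{-1}(\alpha_i)$ through the strictly
   monotone transverse curve $\alpha(r) = \dot D(r, 90^\circ)/\dot
   D(10, 90^\circ)$ on [1, 200] mm. The inverse is a monotone-cubic
   interpolant on a 0.05 mm grid sharpened by safeguarded Newton steps
   (round-trip error below 10⁻⁶ mm). Out-of-range ratios are clamped to
   the nearest bound and the detector down-weighted (weight 0.1) rather
   than dropped, keeping subset sizes fixed.
3. **Initialization**: differencing the squared-distance equations
   $|x - p_i|^2 = r_i^2$ gives a linear system; for a coplanar array the
   out-of-plane coordinate cancels, so (x, y) come from the in-plane
   least-squares solution and z from the median of
   $\sqrt{r_i^2 - \rho_i^2}$, resolved to the patient (+z) side.
   Degenerate geometry falls back to a dose-weighted centroid.
4. **Iterative refinement**: from the current estimate, each detector's
   polar and incidence angles are computed; doses are divided by the full
   angular profile $[G_L(r,\theta)/G_L(r,90^\circ)]\,F(r,\theta)\,
   A(\varphi)$; distances are re-inverted and the weighted nonlinear
   least-squares objective $\sum_i w_i (|x-p_i| - r_i)^2$ re-solved by
   Levenberg–Marquardt with z bounded above the plane. Iteration stops
   when the position moves less than 0.01 mm or after 50 rounds; the RMS
   distance residual and convergence flag are reported.

The angular correction deliberately includes the geometry-function ratio,
not just $F$: the inversion curve assumes $\theta = 90^\circ$ in *every*
factor, and correcting $F$ alone leaves an $O((L/2r)^2)$ bias (~0.05 mm
at clinical distances) that would dominate the noiseless error budget.
With the full profile the forward and inverse models agree exactly at the
true position, and noiseless water-phantom localizations recover every
dwell to well under 0.01 mm. The iterative algorithm is a re-derivation
from the narrative structure of the verification procedure (initial
estimate → angular correction → re-estimation), not a transcription of a
published algorithm.

**CT-density correction.** `wepl_correct()` multiplies each dose by
$\exp(+\mu_{\mathrm{eff}}(\mathrm{WEPL}_i - d_i))$ computed from the
current estimate and re-runs the localization, up to 5 outer rounds. When
the correction shares the forward model's density grid this is an exact
inversion on noiseless data (mean 3D error below 0.01 mm in practice);
with 1 % noise the corrected heterogeneous accuracy is statistically
indistinguishable from the water case. On real data the correction would
inherit CT calibration and registration errors that this closed loop
cannot expose.

## Study driver and statistics

`run_study()` sweeps phantom type (heterogeneous pelvic and its water
override), noise repeats (default 20 per dwell), and detector subset
sizes, localizing all 12 dwells in every cell; everything is
deterministic given the master seed. Errors are reported signed
(estimate − truth) and absolute, per axis and as the 3D vector, aggregated
as mean ± SD (k = 1) in a table whose layout mirrors the field's
convention (rows X/Y/Z/3D, columns by detector count, one decimal place).
Both signed and absolute summaries are emitted because "difference"
tables in the literature are ambiguous between the two.

Group comparisons use the classic pooled-variance Student's t-test
(Welch available via flag) and fixed-effects one-way ANOVA, delegating to
the standard R tests with explicit conventions for degenerate input
(constant samples: t = 0/p = 1 when means agree, p = 0 otherwise; F = 0
for identical groups). The test suite validates both against hand-computed
pooled-variance and sum-of-squares formulas.

A typical 5-repeat study:

```{r study, eval = FALSE}
st <- run_study(study_config(seed = 11, n_repeats = 5))
print(st$table[st$table$axis == "3D", ])
report(st$table, "table1")
```

Under the default conditions the water experiment stays within 1 mm mean
3D error for every subset size (improving monotonically with detector
count), while the heterogeneous experiment shows a positive z bias of
1–2 mm that is statistically significant against water in z only, is
worst for the 9-detector subset, and disappears under the density
correction.

## Numerical choices and degenerate inputs

* Geometry function: on-axis branch taken for $\sin\theta < 10^{-12}$;
  field points inside the active segment on-axis are a domain error.
* Radial dose fit: refuses extrapolation outside the table domain
  (∩ [1, 200] mm); positivity of the fit is checked at construction.
* Anisotropy: bilinear interpolation; rows renormalized exactly at 90°;
  out-of-range queries error at the user surface, while the localization
  loop clamps its internal radius argument to [1, 200] mm (iterates can
  wander before convergence).
* Multilateration: z is constrained ≥ plane + 10⁻³ mm; non-convergence
  returns the best iterate flagged `converged = FALSE` and is recorded,
  not fatal, by the study driver.
* Noise: negative readings (vanishingly rare at σ = 1 %) clamp to zero
  with a warning count; zero-dose detectors are marked unusable.
* WEPL: zero-length rays are an error; rays missing the grid are
  water-equivalent by definition.

## Problem sizes

The shipped defaults — 48 × 48 × 40 voxel grids, 12 dwells, up to
121-detector localizations — run a full 20-repeat, two-phantom,
five-subset study in well under a minute; the test suite uses 1–5-repeat
configurations of the same defaults. These sizes were chosen as the
smallest at which the study's contrasts (water vs heterogeneous, subset
sizes) are cleanly resolved.

## Known limitations

* No photon/electron transport: scatter, spectral hardening and
  detector-silicon effects are outside the model; heterogeneity enters
  only through primary attenuation scaling.
* The bundled TG-43 tables are synthetic stand-ins (see above).
* The pelvic phantom is a geometric caricature of a CT study set; its
  heterogeneity *magnitude* is realistic in sign and order, not
  patient-specific.
* Array-to-patient registration, dwell-time/transit-time estimation and
  real-time streaming are out of scope.
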