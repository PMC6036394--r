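# mplocate

Source position verification for high-dose-rate (HDR) prostate
brachytherapy with a couch-embedded 2D diode array.

During HDR brachytherapy an Ir-192 source is stepped through implanted
catheters by a remote afterloader; small deviations in dwell position can
produce large dose errors, and few tools exist for independent real-time
monitoring. One proposed monitor is an 11 × 11 array of epitaxial diodes
(a "Magic Plate" style array) embedded in the carbon-fibre treatment
couch directly beneath the patient: each diode's dose encodes its
distance to the source, so the dwell position can be recovered by
multilateration. `mplocate` provides a complete, testable simulation of
that verification chain — forward dose model, phantom and plan
generators, reconstruction, and study-level statistics — for medical
physicists who want to quantify how detector count and patient tissue
heterogeneity affect localization accuracy.

## The model

**Forward dose.** Each diode's dose from a dwell at distance r and polar
angle θ (measured from the source long axis, which lies along the
catheter direction) follows the AAPM TG-43U1 line-source formalism:

    D(r, θ) ∝ [ G_L(r, θ) / G_L(r₀, θ₀) ] · g_L(r) · F(r, θ)

with G_L(r, θ) = β / (L·r·sinθ) the line-source geometry function for
active length L = 3.5 mm (1/(r² − L²/4) on the long axis), g_L the
radial dose function, F the 2D anisotropy function, and the reference
point at r₀ = 10 mm, θ₀ = 90°. Tissue heterogeneity scales the water
dose by exp(−μ_eff·(WEPL − r)), where WEPL is the water-equivalent path
length of the source–diode ray through the CT density grid (Siddon
voxel traversal) and μ_eff = 0.111 cm⁻¹ is an effective attenuation
coefficient at Ir-192 energies. Readings carry 1 % multiplicative
Gaussian noise (k = 1).

**Reconstruction.** Diode doses are normalized by the dose D₁₀ of a
detector at 10 mm on the transverse axis in water (α_i = D_i / D₁₀),
inverted to distances through the strictly monotone transverse curve
α(r), and fed to a linearized-multilateration initial estimate followed
by iterative refinement: each round divides the doses by the angular
dose profile at the current estimate (geometry-function anisotropy ×
F(r, θ) × detector directional response), re-inverts, and re-solves the
nonlinear least-squares multilateration. An optional CT-density stage
(`wepl_correct()`) undoes the heterogeneity attenuation from the density
grid and re-localizes.

The bundled g_L and F tables are synthetic stand-ins with the
qualitative shape of published Ir-192 consensus data; consensus tables
can be substituted from plain-text files (`read_radial_dose_table()`,
`read_anisotropy_table()`).

## Worked example

Localize the 12 dwells of the default plan (4 catheters × 3 consecutive
dwells at a 3 mm step) through a heterogeneous pelvic phantom, then apply
the CT-density correction:

```r
library(mplocate)

src  <- source_model()         # L = 3.5 mm Ir-192 line source
plan <- make_dwell_plan()      # 4 catheters x 3 dwells, 3 mm step
mp   <- build_magic_plate()    # 11 x 11 diodes, 10 mm pitch
pelvis <- make_pelvic_phantom(seed = 1)

readings <- score_array(plan, mp, src, phantom = pelvis,
                        noise_sigma = 0.01, seed = 42)
fits <- refine_position(readings, src)
err  <- localization_errors(fits, plan)
round(colMeans(err[, c("dx", "dy", "dz", "d3d")]), 2)
#>    dx    dy    dz   d3d
#> -0.28 -0.02  1.60  2.21

corrected <- wepl_correct(readings, pelvis, fits, src)
err_c <- localization_errors(corrected, plan)
round(colMeans(err_c[, c("dx", "dy", "dz", "d3d")]), 2)
#>   dx   dy   dz  d3d
#> 0.01 0.00 0.02 0.12
```

The uncorrected reconstruction recovers the in-plane (x, y) coordinates
well but overestimates z — the source-to-array distance — by ~1.6 mm on
average, because excess attenuation in tissue, bone and the carbon couch
depresses every dose and the inversion reads that as extra distance.
The density correction removes the bias, leaving ~0.1 mm noise-level
error. Running the same scene with `override_to_water(pelvis)`
reproduces the homogeneous-water case, where accuracy is well within
1 mm without any correction. `run_study()` sweeps detector subset sizes
(9–121, highest-dose detectors first), repeats, and both phantom types,
and `report()` writes a per-axis mean ± SD summary table.

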