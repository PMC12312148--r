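# memphase

Quantitative analysis of lipid membrane phase behavior in fusogenic
liposomes, for membrane biophysicists combining small-angle neutron
scattering (SANS), fluorescence microscopy of giant unilamellar vesicles
(GUVs), fluorescence recovery after photobleaching (FRAP), and static
³¹P solid-state NMR.

Fusogenic lipid mixtures (e.g. DOPE/DOTAP with an aromatic dye) show a
temperature-dependent coexistence of a lamellar phase, a phase of small
vesicles ordered on a body-centered-cubic (BCC) lattice, and large
vesicles. `memphase` implements the forward models and estimators needed
to quantify that coexistence, plus seeded synthetic-data generators that
emulate each measurement so the whole chain can be validated closed-loop.

## Models

**Composite SANS intensity.** The measured curve over
q = 0.002–0.221 Å⁻¹ is modeled as a linear superposition

    I(q) = s_BCC I_BCC(q) + s_ves I_ves(q) + s_lam I_lam(q) + I_B

with free (non-volume-fraction) scale factors and flat incoherent
background I_B:

- `I_BCC ∝ Δρ² V_p P(q) Z(q)`: spheres of radius R (form factor
  `P(q) = [3 j₁(qR)/(qR)]²`) on a BCC paracrystal. Per axis k,
  `Z_k = (1 − |F|²) / (1 − 2|F| cos(a_k·q) + |F|²)` with
  `|F| = exp(−Δa² q²/2)`; the distortion factor is `g = Δa/d_nn`,
  `d_nn = (√3/2) a`. The powder average of `Z = ⟨∏ Z_k⟩` uses an exactly
  symmetrized Gauss–Legendre quadrature (see the methods vignette), with
  a Monte-Carlo oracle as an independent cross-check. Allowed reflections
  satisfy h+k+l even: `q_hkl = (2π/a)√(h²+k²+l²)`.
- `I_ves`: core–shell (solvent-core) vesicle form factor for large
  unilamellar vesicles.
- `I_lam ∝ P_bil(q) Z_N(q)/q²`: stacks of N bilayers of thickness t
  (`P_bil = (sin(qt)/qt)²`) at spacing D with Gaussian spread σ_D
  (`w = exp(−σ_D² q²/2)`), using the lamellar-stack paracrystal
  interference function Z_N (closed form, verified against the direct
  double sum to 1e-10).

Fitting is bounded weighted least squares (Levenberg–Marquardt) with any
parameter subset frozen; scattering length densities default to the D₂O
solvent (6.36×10⁻⁶ Å⁻²) and phospholipid (1×10⁻⁶ Å⁻²) values.

**FRAP.** Traces are normalized by the mean pre-bleach intensity; the
half time t₁/₂ is the time of the post-bleach sample closest to
(I₀ + I_∞)/2; the diffusion coefficient follows the uniform-disk
relation `D = 0.224 r²/t₁/₂` and the mobile fraction
`R = (I_∞ − I₀)/(I_pre − I₀)`. Inside-domain and outside-domain
populations are compared by group means and per-vesicle paired sign
counts.

**GUV membrane profiling.** Gaussian smoothing (σ = 1 px), circular
Hough detection of the vesicle, radial maximum-intensity search within
±10 px of the perimeter, mask building (dilate → fill small holes →
skeletonize), per-angle gray-value profile about the centroid, and
detection of bright membrane domains as contiguous angular runs ≥ 2× the
median baseline.

**³¹P lineshapes.** Static uniaxial chemical-shift-anisotropy powder
patterns (lamellar: maximum at δ⊥ = −20 ppm, shoulder to +45 ppm;
inverted-hexagonal: opposite-sign, roughly half anisotropy, maximum near
+5 ppm; isotropic: Gaussian at 0 ppm), and non-negative least-squares
decomposition of a spectrum into phase fractions.

## Worked example

```r
library(memphase)

## Index the BCC reflections at the fitted lattice constant a = 46 nm
bragg_peaks(lattice_a = 460, q_max = 0.05)
#>   h k l          q
#> 1 1 1 0 0.01931688
#> 2 2 0 0 0.02731820
#> 3 2 1 1 0.03345782
#> ...
```

The (110) and (200) reflections fall at 0.0193 and 0.0273 Å⁻¹ — the
0.02 / 0.027 Å⁻¹ peak pair seen in the measured curves; the lamellar
interference maximum for the 25 nm bilayer spacing sits at 0.025 Å⁻¹.

```r
## Simulate a noisy curve under the study conditions and refit it
truth <- sans_study_params()
sim <- gen_sans_curve(truth, relative_noise = 0.05, seed = 7)
start <- truth
start$bcc$scale <- 2e5; start$vesicle$scale <- 1.5e7
start$lamellar$scale <- 1e-3; start$background <- 0.02
frozen <- setdiff(names(composite_to_vector(truth)),
                  c("bcc.scale", "ves.scale", "lam.scale", "background"))
fit_composite(sim$curve, start = start, frozen = frozen)
#> <sans_fit> chi2_red = 0.9064, converged after 2 iterations
#>   bcc.scale          98572.9 (+/- 2.22e+03)
#>   ves.scale          3.011e+07 (+/- 1.74e+05)
#>   lam.scale          0.000516649 (+/- 8.15e-06)
#>   background         0.0050191 (+/- 6.3e-05)
```

All scale factors land within a few percent of the generating values
(1e5, 3e7, 5e-4, 0.005) with a reduced chi-square near 1.

```r
## FRAP on a synthetic uniform-disk recovery (true D = 2 um^2/s)
frap <- gen_frap_trace(D_true = 2, roi_radius = 0.9, dt = 0.04,
                       duration = 8, noise_sigma = 0.01, seed = 1)
res <- frap_analyze(frap$trace)
#> t_half = 0.08 s, D = 2.27 um^2/s, R = 0.96
```

The ~13% overestimate at this short 8 s observation window comes from
taking I_∞ as the last measured point — the documented behavior of the
estimator on finite traces; on long traces the estimate converges to
within 5% (see the tests).

```r
## Decompose a half-lamellar, half-isotropic 31P spectrum
spec <- gen_nmr_spectrum(weights = c(0.5, 0, 0.5), relative_noise = 0.01,
                         seed = 2)
round(decompose_spectrum(spec$spectrum)$weights, 3)
#>  lamellar hexagonal isotropic
#>     0.524     0.001     0.497
```

## Analysis workflow

The `analysis/` scripts run the full chain on simulated datasets and
write their tables under `results/` (raw simulated data go under
`scratch/data/`):

```sh
Rscript analysis/01_simulate_data.R   # SANS curves, FRAP traces, GUV images, 31P spectra
Rscript analysis/02_fit_sans.R        # composite fits + Bragg indexing
Rscript analysis/03_analyze_frap.R    # D inside vs outside domains
Rscript analysis/04_profile_guvs.R    # membrane profiles + domain detection
Rscript analysis/05_decompose_nmr.R   # phase fractions
```

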