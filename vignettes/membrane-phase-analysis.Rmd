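---
title: "Methods: quantifying membrane phase coexistence in fusogenic liposomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying membrane phase coexistence in fusogenic liposomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphase)
```

# Scope

Fusogenic liposomes made from an inverted-cone lipid (DOPE), a
cylindrical cationic lipid (DOTAP) and an aromatic compound show a
temperature-dependent coexistence of a lamellar phase, small vesicles
ordered on a body-centered-cubic (BCC) lattice, and large unilamellar
vesicles. `memphase` implements the quantitative chain used to
characterize that coexistence: a composite SANS forward model with
fitting, FRAP diffusion estimation, GUV membrane profiling with
bright-domain detection, ³¹P powder-lineshape simulation with mixture
decomposition, and seeded generators that emulate each measurement.
Everything upstream of these analyses (instrument reduction, cryo-EM
reconstruction, wet-lab protocols) and all mechanistic interpretation is
out of scope.

# The composite SANS model

The measured intensity over q = 0.002–0.221 Å⁻¹ is

$$I(q) = s_\mathrm{BCC} I_\mathrm{BCC}(q) + s_\mathrm{ves} I_\mathrm{ves}(q)
       + s_\mathrm{lam} I_\mathrm{lam}(q) + I_B.$$

The scale factors are free amplitudes: they absorb different physical
prefactors per term (excluded lattice volume, shell volume fraction,
membrane mass per area) and are therefore *not* mutually comparable
volume fractions, though each tracks the abundance of its phase.

## BCC paracrystal of small vesicles

`bcc_intensity()` is `scale · Δρ² V_p P(q) Z(q)` with the sphere form
factor `P(q) = [3 j₁(qR)/(qR)]²` and the paracrystal structure factor
`Z`. Along each primitive-cell axis k,

$$Z_k(\vec q) = \frac{1 - |F|^2}{1 - 2|F|\cos(\vec a_k \cdot \vec q) + |F|^2},
\qquad |F| = e^{-\Delta a^2 q^2 / 2},$$

where the primitive vectors are the cube body diagonals
`a/2 (−1,1,1)`, `a/2 (1,−1,1)`, `a/2 (1,1,−1)`, and the Gaussian lattice
displacement Δa defines the distortion factor `g = Δa/d_nn` with the
nearest-neighbor distance `d_nn = (√3/2) a`. Δa is taken isotropic and
identical on all three axes. The paracrystal becomes an ideal lattice as
`g → 0` (singular on-peak; the implementation caps `|F|` at `1 − 1e−12`)
and structureless (`Z → 1`) for large `g`.

**Powder average.** `Z(q) = ⟨∏_k Z_k⟩` must be averaged over crystal
orientations. The product over the three primitive diagonals is
invariant under inversion and under permutations of the coordinate
axes, but *not* under single sign flips: flipping one axis exchanges one
of the three diagonals for the fourth body diagonal. A naive reduction
of the integration domain to one octant is therefore invalid. Instead
the integrand is first symmetrized exactly: averaging the product over
the four leave-one-out triples of the four body diagonals leaves the
full powder average unchanged (each triple's spherical average equals
any other's, by the same change of variables), and the symmetrized
integrand *is* invariant under the full achiral cubic group. It is then
integrated with a Gauss–Legendre product rule over the octant
(`cos θ × φ ∈ [0,1] × [0,π/2]`, default 150 × 150 nodes), which puts
four times the node density of a hemispherical rule where the sharp
paracrystal ridges need it. `bcc_lattice_factor_mc()` provides an
independent Monte-Carlo oracle that averages the *raw, unsymmetrized*
triple product over the full sphere, so agreement between the two also
validates the symmetrization identity.

**Validity window.** As `q → 0`, `|F| → 1` and the integrand develops
quasi-singular ridges of angular width ∝ (1 − |F|) that no fixed
orientation grid resolves; every fixed-quadrature implementation of
paracrystal powder averages shares this limitation. At the default
`g = 0.1` the quadrature is stable to ≤ 0.1% under grid doubling for
q ≥ 0.006 Å⁻¹ (for `g = 0.05`, q ≥ 0.015 Å⁻¹); the package asserts its
quadrature invariants on that validated window. The affected low-q
region carries negligible BCC intensity (the vesicle and lamellar terms
dominate there), so composite fits are insensitive to it.

## Large vesicles and lamellar stacks

`vesicle_intensity()` is the standard core–shell sphere with solvent
core: the two amplitude terms carry *opposite* contrast signs,

$$A(q) = 3V_c(\rho_s - \rho_m)\frac{j_1(qR_c)}{qR_c}
       + 3V_t(\rho_m - \rho_s)\frac{j_1(qR_t)}{qR_t},$$

so that `I(0) = scale · φ V_shell Δρ²`. (A same-sign pair of terms does
not describe a hollow shell — its forward limit would involve the total
volume rather than the shell volume; the implementation follows the
standard model.)

`lamellar_intensity()` is `scale · P_bil(q) Z_N(q)/q²` with
`P_bil = (sin qt / qt)²`; the `2πΔρ²Γ_m` prefactor is absorbed into the
scale. The stack interference function `Z_N` is the one-dimensional
paracrystal of N layers at spacing D with Gaussian spacing spread σ_D
(`w = exp(−σ_D² q²/2)`), implemented in closed form with

$$a_N = 4w^2 - 2(w^3{+}w)\cos qD - 4w^{N+2}\cos NqD
      + 2w^{N+3}\cos[(N{-}1)qD] + 2w^{N+1}\cos[(N{+}1)qD],$$

the five-term numerator of the standard lamellar-stack paracrystal
model; a common four-term transcription (without the last term) fails
against the direct double sum by orders of magnitude, while this form
agrees to better than 1e−10 relative for all integer N ≤ 10 — the
package tests assert exactly that. Near the interference peaks the
closed form loses ~`eps/den²` digits to cancellation, so for
denominators `1 + w² − 2w cos qD < 0.01` the implementation switches to
the numerically stable direct sum. Non-integer N mixes stacks of
`⌊N⌋` and `⌊N⌋+1` layers with weight `x_N = 1 − (N − ⌊N⌋)`, the
convention of standard implementations. `Z_1 = 1` exactly, and the q = 0
divergence of the `1/q²` factor restricts evaluation to q > 0.

## Fitting

`fit_composite()` minimizes `Σ [(I_model − I)/σ]²` (unit weights when no
uncertainties are present) with bounded Levenberg–Marquardt
(`minpack.lm`). Any subset of the 18 flat parameters can be frozen; the
defaults freeze the SLDs at the D₂O/phospholipid values and the vesicle
volume fraction φ, which is exactly degenerate with the vesicle scale
factor. Length parameters are bounded to 0.1–10× their start, scales
and background to `[0, ∞)`, the layer count to `[1, 10N₀]`. Starting
geometry encodes the microscopy-derived values: bilayer 30 Å, BCC
vesicle radius 250 Å, nearest-neighbor distance 450 Å, large-vesicle
radius 5000 Å, lamellar spacing 250 Å. Since "lattice constant" and
"nearest-neighbor distance" are often used loosely for this system, the
package exposes the cubic cell edge `a` as the primitive parameter and
documents the strict conversion `d_nn = (√3/2) a` (450 Å ↔
a = 519.6 Å). The expensive orientation average depends only on
`(a, g, n_orient, q)` and is memoized, so fits with frozen lattice
geometry pay for one `Z` evaluation regardless of iteration count.
Non-convergence is flagged on the result, not raised. Parameter
uncertainties are `sqrt(diag((JᵀJ)⁻¹) · χ²_red)`.

Instrument resolution smearing (the measurement used Δλ/λ = 10%) is not
applied; all reported quantities are unsmeared. `bragg_peaks()` indexes
the allowed reflections (`h+k+l` even) for reference lines and peak
assignment.

# FRAP

The estimators follow the half-time protocol exactly: intensities are
normalized by the mean pre-bleach value; `I₀` is the first post-bleach
sample (no bleach-profile fit); `I_∞` is literally the last measured
point (no asymptote fit); `t₁/₂` is the time from the `I₀` sample to the
post-bleach sample whose intensity is nearest to `(I₀+I_∞)/2`, ties
resolved to the earlier sample, no interpolation. Then
`D = 0.224 r²/t₁/₂` and `R = (I_∞−I₀)/(I_pre−I₀)`. Arbitrary non-uniform
time grids are accepted (observation intervals in practice ranged from
2.4 to 10 s at ~40 ms steps, with ROI radii 0.4–1.8 μm).

**Known limitation.** Taking `I_∞` from a finite trace biases `t₁/₂`
low — and `D` high — by roughly `3.6 τ_D/T` (T the post-bleach
duration, `τ_D = r²/4D`), e.g. ~13% for an 8 s trace at
D = 2 μm²/s, r = 0.9 μm. The recovery-accuracy tests therefore use
durations ≥ 150 `t₁/₂`, where the estimator is within 5% across
D ∈ [0.5, 5] μm²/s and r ∈ [0.4, 1.8] μm. No acquisition-photobleaching
correction is applied, and the ~2× substrate-adhesion slowdown of
supported membranes is deliberately not corrected for: reported D values
are as-measured.

The synthetic generator uses the uniform-disk diffusive recovery
`f(t) = e^{-2\tau_D/t}[I_0(2\tau_D/t) + I_1(2\tau_D/t)]` with
`τ_D = r²/(4D)` — the model from which the 0.224 constant derives: the
numeric root of `f = 1/2` gives `t₁/₂ = 0.2240 r²/D`, so the generator
and the estimator are exactly self-consistent. (With the occasionally
quoted `τ = r²/2D` convention the half time would come out at
`0.448 r²/D`, inconsistent with the 0.224 relation; the package uses the
`r²/4D` form.) `compare_frap_groups()` reports group means, standard
deviations, the outside/inside ratio of means, and — when vesicle
identifiers permit pairing — the count of vesicles with strictly slower
inside-domain diffusion.

# GUV membrane profiling

The pipeline mirrors the established image-analysis recipe: Gaussian
smoothing (σ = 1 px, separable convolution with reflective boundaries so
constant images and total intensity are preserved), circle detection,
radial maximum search, mask building, angular profile, domain
detection. Conventions: x = column, y up, angles counterclockwise from
the +x axis; pixel size 64 nm by default; no operation mutates its
input.

- **Detection** (`detect_vesicle_circle()`): gradient-direction circular
  Hough transform. Sobel gradients; pixels above the 0.97
  gradient-magnitude quantile vote at `p ± r ĝ` for each candidate
  radius; votes disperse over neighboring cells, so 5×5 neighborhood
  sums are scored. The center is refined by a vote-weighted centroid;
  the radius by the argmax of the angular-mean radial intensity
  profile, because the two gradient shells flank the intensity ridge by
  about the membrane width. Featureless images raise a classed
  detection error.
- **Radial search** (`radial_max_positions()`): rays of total length 5×
  the radius through the center at 1° increments (360 by default,
  configurable); bilinear sampling at 0.25 px steps; the maximum is
  taken within ±10 px of the perimeter, so a decoy structure outside
  that window can never capture the profile. Rays leaving the image are
  skipped and recorded.
- **Mask** (`build_membrane_mask()`): rasterized points → disk dilation
  (radius 2 px, the smallest that reliably closes the ≤1 px gaps of 1°
  sampling) → filling of holes below 50 px² (the vesicle interior, a
  large hole, is preserved) → Zhang–Suen thinning to a one-pixel,
  8-connected closed curve. Open contours are flagged, not raised.
- **Profile** (`angular_profile()`): per skeleton pixel, angle about the
  detected centroid and gray value from the *smoothed* image (the
  detection input; configurable by passing a different image), sorted by
  angle with coincident angles averaged.
- **Domains** (`detect_domains()`): baseline = median profile intensity;
  contiguous circular runs ≥ 2× baseline (the observed elevation of
  bright membrane spikes over control vesicles) spanning ≥ 5° are
  reported with extent and mean fold-elevation. The threshold and
  minimum span are parameters; domain counts are non-increasing in the
  threshold.

No quality filter is applied to the radial maxima before mask building
(none is part of the recipe); the Hough accumulator thresholds were
calibrated once on synthetic rings at signal-to-noise 5–10.

# ³¹P powder lineshapes

For uniaxial chemical-shift anisotropy the resonance at crystallite
angle θ is `δ(θ) = δ⊥ + (δ∥ − δ⊥)cos²θ`; with cos θ uniform over a
powder the frequency density is
`p(δ) = 1/(2√((δ − δ⊥)(δ∥ − δ⊥)))` between the edges — an integrable
singularity at δ⊥ (the pattern maximum) and a shoulder to δ∥. The
implementation accumulates exact per-bin masses from the closed-form
CDF `√((δ−δ⊥)/(δ∥−δ⊥))` (no numerical trouble at the singular edge),
convolves with a Gaussian, and normalizes to unit area.

Default bases encode the observed landmarks: lamellar δ⊥ = −20 ppm,
δ∥ = +45 ppm (the shoulder is a bound near +50 ppm, not a fitted value;
δ∥ is a parameter); inverted-hexagonal δ⊥ = +5 ppm, δ∥ = −27.5 ppm —
opposite-sign anisotropy of half magnitude, the geometric consequence
of fast lateral diffusion around the H_II cylinders; isotropic:
Gaussian at 0 ppm. Broadening defaults to σ = 1 ppm: convolution shifts
the apparent maximum of the one-sided edge singularity inward by
≈ 0.77σ, and 1 ppm (a realistic static ³¹P line width) keeps the
simulated lamellar maximum within 1 ppm of the −20 ppm landmark, which
σ = 2 ppm would not.

`decompose_spectrum()` solves a non-negative least-squares problem
against unit-area basis lineshapes on the spectrum's grid
(`pracma::lsqnonneg`), returning weights in area units plus the relative
residual; linearly dependent basis sets are rejected. The underlying
measurement analysis was qualitative; this decomposition is the
package's minimal quantitative counterpart, and its weights should be
read as relative phase amounts under the assumed basis shapes.

# Synthetic data and what passing tests show

Each generator is a pure function of its parameter set including the
seed (bit-reproducible) and returns ground truth alongside the data:

- `gen_sans_curve()`: composite model on a 150-point log-spaced grid
  over 0.002–0.221 Å⁻¹ with multiplicative Gaussian noise (default 5%,
  the counting-statistics scale of the measured curves) and
  `σ = rel · I_true`. The default truth (`sans_study_params()`) uses the
  microscopy-derived geometry with scale factors balanced so every term
  is identifiable: vesicle-dominated low-q shoulder, BCC peaks at
  0.017/0.024 Å⁻¹ (a = 519.6 Å), lamellar maximum at 0.025 Å⁻¹,
  background floor at high q.
- `gen_guv_image()`: radial Gaussian ring (width 2 px, amplitude 100
  over background 10) with box angular domains of given fold-elevation,
  additive Gaussian noise, clipped at zero; 256² px, 64 nm pixels.
- `gen_frap_trace()`: uniform-disk recovery with pre-bleach plateau,
  bleach depth, mobile fraction and additive noise; 40 ms default
  sampling.
- `gen_nmr_spectrum()`: weighted mixtures of the default bases with
  additive noise.

Noise models are additive Gaussian for images and traces and relative
Gaussian for scattering — the dominant noise of each modality. What the
generators deliberately do **not** emulate: optical point-spread
blurring and out-of-focus membrane contributions, vesicle shape
fluctuations and adhesion footprints, acquisition photobleaching,
instrument resolution smearing, baseline roll and phasing errors in
spectra, and any correlated noise. Closed-loop tests passing on this
synthetic layer therefore demonstrate the correctness and calibration of
the estimators under their stated models, not their robustness to every
artifact of real data.

# Problem sizes and test design

The test suite runs the fit-recovery study at 50 seeded replicates of
150-point curves at 5% noise (free scale factors and background;
≥ 90% of replicates must land within 20% of truth), the GUV closed loop
at 20 seeded images at signal-to-noise 5 with 2.5-fold domains (centers
recovered within 5°), FRAP recovery over a 3 × 5 grid of radii and
diffusion coefficients (within 5% noise-free), and the NMR
decomposition noise-free (within 2%) and at 1% noise over 20 seeds
(RMSE < 5%). These sizes keep the whole suite under a minute on a
single CPU while leaving each check statistically meaningful; the
`analysis/` drivers use the same study conditions at small replicate
counts and print what they find.

# Known limitations

- The BCC orientation average is a fixed quadrature: accuracy degrades
  below the validated low-q window stated above (where the BCC term is
  negligible anyway).
- The FRAP half-time estimator inherits the finite-trace I_∞ bias and
  the half-sample discretization of the nearest-sample rule.
- Hough detection assumes one dominant ring; fields with several
  comparable vesicles require cropping.
- The ³¹P decomposition assumes the basis lineshapes are correct up to
  amplitude; chemical-shift drifts or intermediate-exchange lineshapes
  are not modeled.
- Scale factors from SANS fits are comparable across conditions for the
  same term, but not across terms.
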