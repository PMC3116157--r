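---
title: "Three-state equilibrium unfolding: model, fitting and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state equilibrium unfolding: model, fitting and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldfit)
```

## The model

A protein equilibrated in guanidine hydrochloride (GdnHCl) populates, for
the systems this package targets, three conformational states: native (N),
a molten-globule intermediate (I) and unfolded (U), in the linear
equilibrium N ↔ I ↔ U. Each transition is described by the linear
extrapolation method (LEM): its unfolding free energy falls linearly with
denaturant concentration,

$$\Delta G_{NI}([D]) = \Delta G^0_{NI} - m_{NI}[D], \qquad
  \Delta G_{IU}([D]) = \Delta G^0_{IU} - m_{IU}[D],$$

with $\Delta G^0$ in kcal/mol and the m-value in kcal mol⁻¹ M⁻¹
(proportional to the change in solvent-exposed surface). Equilibrium
constants are $K = e^{-\Delta G/RT}$ with
$R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹ and default $T = 298.15$ K
(titrations equilibrated at 25 °C). The populations follow from the
Boltzmann weights $1, K_1, K_1K_2$:

$$f_N = \frac{1}{Z},\quad f_I = \frac{K_1}{Z},\quad f_U = \frac{K_1K_2}{Z},
  \qquad Z = 1 + K_1 + K_1 K_2.$$

The recorded observable — here the tryptophan-fluorescence emission
maximum λmax — is modelled as the population-weighted mixture of per-state
baselines,

$$Y([D]) = \sum_{s \in \{N,I,U\}} f_s([D])\,\bigl(b_s + \sigma_s [D]\bigr).$$

Two assumptions deserve emphasis:

* **LEM linearity.** The linear $\Delta G$–$[D]$ form is the standard
  treatment for GdnHCl titrations and is adopted as-is; no
  denaturant-activity correction is applied.
* **λmax as a linear observable.** The peak wavelength of a mixture of
  emission bands is not exactly the population-weighted mean of the
  component peaks. Treating it as one mirrors universal fitting practice
  for λmax transition curves; with the generator's default band width
  (σ = 20 nm) and band separation (≤ 19 nm), the discrepancy between the
  mixture-spectrum peak and the weighted mean stays below 0.5 nm across
  the transition region (checked in the test suite), comparable to the
  default measurement noise.

The two-state model (`two_state_params`) is the $K_2 \to 0$ degenerate
limit with $f_I \equiv 0$; it exists so that the three-state claim can be
justified from data rather than assumed.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `dg0`, `m` per transition | kcal/mol, kcal mol⁻¹ M⁻¹ | fitted | the quantities of interest; `m > 0` enforced |
| `baseline_n/i/u` | nm (for λmax) | fitted; generator 336/341/355 | typical λmax of buried, molten-globule and exposed Trp |
| `baseline_slope_*` | nm/M | 0 | λmax plateaus are flat in practice; slopes available for intensity signals |
| `temperature` | K | 298.15 | titrations equilibrated at 25 °C |
| `noise_sd` (curves) | nm | 0.3 | nm-scale scatter typical of λmax readouts |
| `conc_grid` | M | 31 points, 0–3 M | covers both midpoints (≈0.9 and ≈2.0 M) of the built-in panel |
| destabilization threshold | kcal/mol | 2.0 | conventional cutoff for a clearly destabilizing mutation |

The built-in panel (`hcaii_p237_panel()`) carries the published three-state
point estimates for pseudo wild-type human carbonic anhydrase II
(HCAII_pwt, C206S) and the five Pro237 substitutions with full component
fits (P237A/T/N/I/F). P237H is represented only by its literature total
ΔΔG_NU of 7.3 kcal/mol, because its component transitions were never
resolved; `build_stability_table()` therefore supports `literature`
records carrying a ΔΔG without component free energies. The λmax baselines
336/341/355 nm are generator defaults chosen as field-typical values —
they are **not** published measurements and are overridable.

## Fitting

`fit_curve()` minimizes the residual sum of squares between the observed
signal and $Y([D])$ over the free parameters (4 for two-state, 7 for
three-state with flat baselines) with bounded Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`): m-values are constrained positive
(lower bound 10⁻⁶) and baselines to the observed signal range extended by
one span, which keeps the sigmoid model identifiable without biasing
interior solutions. Numerical choices:

* **Starting values** (`initial_guess()`): N/U baselines from the means of
  the first/last 15% of points; the intermediate baseline midway between
  them; transition midpoints where the normalized signal crosses 25% and
  75% of the N→U span; m-values start at the field-typical 6 and 4
  kcal mol⁻¹ M⁻¹ (5 for two-state), and $\Delta G^0 = m \times C_m$.
* **Convergence**: relative tolerance 10⁻¹⁰ on the residual sum of
  squares, at most 1024 iterations (the underlying routine's cap).
* **Multi-start fallback**: if the single start fails, five seeded
  multiplicative jitters (±30%) of the start are tried and the best result
  returned; deterministic given `seed`.
* **Degenerate inputs**: flat curves (signal span within a
  second-difference noise floor) are rejected before fitting; curves with
  fewer points than free parameters + 3 are rejected; a rank-deficient
  Jacobian (e.g. an invisible intermediate) yields `NA` standard errors
  with a warning rather than a silent failure.
* **Overflow**: exponents in $e^{-\Delta G/RT}$ are clamped at |x| = 700
  with a warning; relevant only for pathological parameter values.

Standard errors default to the Jacobian-based covariance scaled by
RSS/(n−p) — the asymptotic estimate every standard fitting program
reports. Because the provenance of published ± values for this kind of
table (asymptotic vs replicate spread) is generally unstated, a seeded
case-resampling bootstrap (`n_bootstrap > 0`) is offered as the
alternative; the test suite checks the two agree within a factor of a few
on well-behaved curves.

Curves are fitted per variant with independent m-values — no global
shared-m fitting — mirroring how per-variant m-value tables are produced.

`select_model()` fits both models and compares small-sample-corrected AIC
(AICc, with k counting the residual variance); differences below 2 are
flagged ambiguous and resolved toward the two-state model on parsimony
grounds.

## λmax extraction

`extract_lambda_max()` offers three estimators. The default is a 3-point
parabolic refinement of the discrete maximum: it gains sub-grid precision
from 1-nm instrument sampling without assuming a band shape. A maximum on
the window edge is an error (the window clipped the band) rather than a
silently returned boundary value; ties in the discrete maximum break
deterministically toward the lower wavelength; the `centroid` variant uses
an intensity-weighted mean above 80% of the peak. How instruments
interpolate their reported λmax is generally undocumented, so the
parabolic default is a package choice, not a reproduction of any
instrument's firmware.

## The synthetic-data generator

`generate_curve()` adds iid Gaussian noise (default SD 0.3 nm) to the
model signal on the default 31-point, 0–3 M grid. `generate_spectra()`
builds each spectrum as the population-weighted sum of Gaussian emission
bands (σ = 20 nm) centred at the per-state baselines, sampled at 1 nm over
300–450 nm, with intensity noise whose default (10⁻³ of peak height) makes
the extracted-λmax scatter ≈ 0.3 nm — consistent with the curve
generator. All randomness flows through one explicit seed (replicate r of
variant i shifts the seed deterministically), and generators restore the
caller's RNG stream.

What the generator emulates: three-state λmax transition curves with the
published thermodynamics, flat baselines, homoscedastic noise, Gaussian
emission bands. What it does not: concentration-dependent
(heteroscedastic) noise, baseline drift, inner-filter and Raman artifacts,
asymmetric emission bands, pipetting error in the denaturant series.
Passing recovery tests on these synthetics therefore demonstrates that the
estimator is correct and well-conditioned under the assumed noise model —
not that real titrations are free of the systematic effects listed above.

## What the checks compute, at which sizes

The test suite and `scripts/acceptance.R` work at the study's native
sizes: 31-point curves over 0–3 M, six variants, and 100 seeded noisy
replicates (σ = 0.3 nm) of the reference variant for the stochastic
recovery check; property-style tests use denser grids (up to 201 points)
for monotonicity and an independent Boltzmann-weight oracle for the
populations. On noiseless curves the full pipeline
(generate → fit → stability table) returns every ΔG, m, ΔG_NU and ΔΔG_NU
of the generating panel to within 1% (in practice to ~10⁻¹²); across the
100 noisy replicates the mean fitted ΔG_NI and ΔG_IU of the reference lie
inside the published ±0.6 bands.

One honest caveat the analysis workflow makes visible: a *single* noisy
realization at σ = 0.3 nm carries ΔG_NU standard errors near 1 kcal/mol,
so per-variant ΔΔG estimates from one curve scatter accordingly and the
2 kcal/mol classification is only reliable for large effects (such as the
7.3 kcal/mol literature record). The published ±0.6 uncertainties
correspond to the lower noise of averaged instrument scans; the
classification acceptance check accordingly uses the noiseless
reconstruction, and the stochastic check tests the *mean* over replicates.

## Sign convention and other open choices

* **ΔΔG sign**: defined as ΔG_NU(reference) − ΔG_NU(mutant), so
  destabilizing mutations are positive. Verbal descriptions of this
  subtraction are often stated in the opposite order while the printed
  values are positive; the positive-is-destabilizing convention is fixed
  here and `ddg_nu()` is antisymmetric under argument exchange.
* **Predictor comparison**: matching is by variant label; Pearson r, RMSE
  and the maximum-absolute-deviation variant are reported, with unmatched
  variants surfaced as warnings rather than silently dropped. The bundled
  predictor table (`foldx_ddg_synthetic.tsv`) contains two published
  predictor values (P237H 1.03, P237I 1.22 kcal/mol) and synthetic ~1
  kcal/mol placeholders for the remaining variants, as its header states;
  running the predictor itself (a licensed external program plus a crystal
  structure) is out of scope, so only its tabular output format is
  supported.
* **Error propagation for ΔΔG** assumes independent fits between variants
  (no cross-covariance), which is exact for separately measured curves.

## Limitations

Kinetics, thermal denaturation (ΔCp, Gibbs–Helmholtz), models with more
than three states, global multi-curve fitting with linked parameters,
Bayesian posterior sampling, and spectral deconvolution into component
bands are all out of scope.
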