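---
title: "Models and methods behind specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind implements the linear-analysis chain that biophysical
spectroscopy papers apply to protein–ligand (and protein–nanoparticle)
titrations. This vignette records the models, the assumptions behind them,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Quenching model

The Stern–Volmer relation, F0/F = 1 + K_SV [Q], assumes a single class of
equally accessible fluorophores and one quenching channel. Real
protein–nanoparticle data frequently curve: quenching is efficient
(static, via a ground-state complex) at low ligand concentration and
weaker (dynamic, collisional) once the accessible surface saturates.
`fit_two_regime_sv()` therefore fits two independent ordinary
least-squares lines split at a breakpoint concentration, each needing at
least three points.

Choices and defaults:

* **Intercept.** The theoretical intercept is 1, but plotted fits in the
  literature are usually unconstrained. The default is unconstrained OLS,
  with the deviation of the intercept from 1 reported in `tidy()` as a
  diagnostic (`intercept_dev`); `force_unit_intercept = TRUE` regresses
  (F0/F − 1) through the origin instead. Note that for a second regime the
  unconstrained intercept is *expected* to differ from 1 — it absorbs the
  quenching accumulated in the first regime.
* **Breakpoint.** Default 15 µM, the customary choice for weak-binder
  titrations spanning 2–100 µM; `"auto"` scans every interior split that
  leaves ≥ 3 points per side and keeps the split with the smallest total
  residual sum of squares. Because a continuous kink lies on *both*
  segment lines, ties are resolved to the **largest** candidate, matching
  the convention that the breakpoint concentration belongs to the first
  regime.
* **Lifetime.** τ0 = 6 ns, the accepted unquenched tryptophan lifetime;
  k_q = K_SV/τ0 exactly (an algebraic identity, tested as such).
* **Mechanism thresholds.** The diffusion-controlled collisional limit is
  taken as 1e10 1/(M s). A regime is *static* when k_q exceeds
  `static_factor` (default 100) times that limit, i.e. 1e12 1/(M s);
  between the limit and the factor it is *dynamic*; below the limit it is
  dynamic with a sub-collisional note. Any cutoff between roughly 60 and
  480 times the limit separates the same datasets; 100 is the round
  decade, and the thresholds are echoed into every classification's
  rationale string.
* **Linearity.** The single-line and two-line fits are compared by an
  F-ratio (default threshold 10); an essentially perfect single line
  (RSS ≤ 1e-12 × TSS) short-circuits to "linear" so that noiseless data do
  not divide zero by zero.

## Binding isotherm

`fit_double_log()` fits log10((F0 − F)/F) on log10([Q]) by OLS: the
intercept is log10(Kb), the slope the site number n. Base-10 logarithms
are the literature convention and are required for Kb = 10^intercept.
Points with F ≥ F0 have no defined logarithm and are excluded with a
warning; at least three admissible points are required. Concentrations
enter in molar. Because Kb is dimensionally 1/M^n when n ≠ 1, its
magnitude depends on the concentration unit; the fitted object carries
this caveat (`unit_caveat`) rather than silently rescaling.

## Thermodynamics

`vant_hoff_fit()` is OLS of ln Kb on 1/T, assuming ΔH° and ΔS° constant
over the examined range (no heat-capacity term): ΔH° = −slope·R,
ΔS° = intercept·R with R = 8.314 J/(mol K) exactly. Two temperatures
determine the line exactly and trigger a zero-degrees-of-freedom warning.
ΔG°(T) is computed from the Gibbs–Helmholtz identity ΔG° = ΔH° − TΔS°,
*not* from −RT ln Kb; the two agree only when the van't Hoff line is
exact, and reporting the identity keeps ΔG° exactly consistent with the
reported ΔH°/ΔS° at every temperature. `vant_hoff_consistency()` exists
because published ΔH°/ΔS° values sometimes cannot be reproduced by an OLS
fit of the published binding constants (weighting, rounding, or a
different estimator); it reports relative differences against a supplied
reference and warns beyond a 5% default tolerance instead of guessing
which number is right.

Force classification follows the sign rules (negative/negative → hydrogen
bond + van der Waals, positive/positive → hydrophobic, negative ΔH° with
positive ΔS° → electrostatic). A noise guard ε (default 100 J/mol) keeps
numerically-zero estimates unclassified; for the entropy the guard is
ε/298.15 K — the same energy scale spread over a room-temperature kelvin —
since a guard of ε per single kelvin would swallow physically meaningful
entropies of tens of J/(mol K).

## Peak location

All fluorescence analyses reduce a scan to its peak. `peak_intensity()`
takes the discrete maximum (ties to the lowest wavelength) and refines it
with an iterated least-squares parabola fitted around the running centre
(default half-width 25 nm). When every intensity in the fit window is
positive the parabola is fitted to **log** intensity: a Gaussian band is
exactly quadratic in the log domain, so the refinement is unbiased for any
window placement and dramatically more noise-robust than a 3-point
interpolation. On a 1 nm grid with 1% multiplicative noise and a
sigma = 15 nm band, the shift between two peak estimates has a standard
deviation of about 0.03 nm (versus about 0.11 nm for a linear-domain
parabola, whose error tail crosses 0.25 nm). Far-tail points below 20% of
the window maximum are dropped to bound the log-noise amplification;
non-positive data (e.g. CD traces) fall back to a linear-domain and
ultimately 3-point parabola. Because the refinement is linear in the
data (and the log fit shifts by a constant under scaling), F0/F ratios of
same-shaped bands are exact to machine precision — the property that makes
noiseless parameter recovery exact.

The synchronous shift verdict (red/blue/none) uses a 1 nm threshold by
default: shifts below the sub-grid refinement's trustworthy resolution
should not be over-interpreted.

## Melting temperature

`melting_tm()` smooths the trace with a Savitzky–Golay filter (window 7,
degree 2 — a local quadratic, wide enough to suppress 1% noise without
flattening a ~10 °C transition), takes central differences, and refines
the extremum of |dF/dT| with a least-squares parabola over the
neighbouring points (window-matched, ±4 grid steps). On 1 °C grids this
recovers midpoints to ≈ 0.15 °C at 1% noise. A curve whose derivative has
no pronounced extremum — flat, or purely linear drift — raises a
"no transition" error; the criterion is that the derivative maximum must
exceed 1.5× the median |dF/dT| and a numerical floor of 1e-10 times the
signal magnitude.

## Circular dichroism and colloidal stability

Mean residue ellipticity is the definitional rescaling
MRE = Θ/(10 C_p n l); the α-helix fraction maps MRE at 208 nm linearly
between the coil (−4000) and pure-helix (−33000) basis values, reporting
both the raw and the [0, 100]-clamped percentage. No basis-set
deconvolution is attempted. The zeta-potential rule classifies |ζ|:
above 30 mV good, 5–30 mV short-term, below 5 mV fast aggregation; the
boundary values 5 and 30 mV are assigned to the middle class (closed
interval), a convention the qualitative rule leaves open.

## The synthetic-data generator

No deposited raw spectra exist for this kind of experiment, so
`ground_truth()` + `generate_*()` stand in for the instrument, and every
generated dataset carries the truth that produced it. Defaults, chosen
once as representative of a lysozyme-like titration:

| component | default | note |
|---|---|---|
| emission band | Gaussian, 340 nm, σ 25 nm, grid 300–450 nm, 1 nm | tryptophan emission; scan range is a choice, instruments vary |
| synchronous bands | σ 15 nm at 280 nm (Δλ=60) / 290 nm (Δλ=15), grid 250–400 nm | synchronous bands are narrower than emission bands |
| SV law | K_SV = 29.25e3 then 3.492e3 1/M, breakpoint 15 µM, piecewise-continuous | a regime-wise generative law, not a microscopic mixed-quenching model |
| isotherm | Kb = 105.07 1/M, n = 0.56 | weak binder, fractional site number |
| thermodynamics | ΔH° = −90.89 kJ/mol, ΔS° = −282.11 J/(mol K) | Kb(T) generated van't Hoff-consistently |
| melt | two-state, Tm 71.25 °C, ΔH_m 400 kJ/mol, linear baselines 1000 − 2T and 250 − 0.5T a.u., 25–90 °C at 1 °C | the two-state model with linear baselines is the standard minimal choice |
| ANS | linear rise from 100% to 300% of control at 15 µM, flat beyond | the plateau level is a choice; only "dramatic increase" is typically reported |
| far-UV CD | double-minimum template scaled so Θ(208) inverts the MRE relation exactly, target −15000 deg cm²/dmol | mostly-helical protein |
| noise | 1% multiplicative Gaussian per grid point, seeded | photomultiplier-like; `withr::with_seed` restores RNG state |

What the generator does *not* emulate — and what green recovery tests
therefore do not certify on real data: inner-filter absorption,
wavelength-dependent instrument response and drift, correlated (non-white)
noise, scattering baselines from aggregating nanoparticles, FRET, and any
deviation of real band shapes from a Gaussian. The recovery suite
certifies the *estimators* (analysis ∘ generation = identity at zero
noise; calibrated errors at 1% noise), not the physics.

## Problem sizes and determinism

Tests and the acceptance script run titrations of 7–9 concentrations on
151-point grids, 66-point melting curves, and stochastic repetitions of
100 seeds — the sizes of the experiments being emulated, so the whole
suite completes in well under a minute of fit time. Generators accept an
explicit `seed` and restore the RNG state afterwards; identical truth and
seed give byte-identical datasets.

## Interfaces

This is an analysis library rather than a shell tool: the workflow entry
point is `run_pipeline()` on a `pipeline_config()`, which executes every
stage whose input is present, records per-stage errors without aborting
the rest, echoes every threshold into the report, and serialises with
`report_json()`. File exchange uses a deliberately plain CSV dialect with
a `#` key:value header; numbers are written at 17 significant digits and
parsed with base R's correctly-rounded reader, so write → read is
bit-exact (the reason the canonical concentration column is molar:
µM↔M conversion is not exactly invertible in binary floating point,
though µM instrument exports are accepted on input).

## Known limitations

* The two-regime fit is a descriptive split, not a mechanistic
  mixed-quenching model; the auto-breakpoint is only identified when both
  sides retain three points.
* Kb for n ≠ 1 is unit-dependent (see above); cross-study comparisons
  must match conventions.
* The van't Hoff analysis assumes temperature-independent ΔH°/ΔS°; no
  ΔCp term is offered, and standard errors are plain OLS errors.
* Near-UV CD shifts reuse the peak machinery but no numeric claims are
  attached; CD secondary-structure deconvolution and DLS/zeta raw-signal
  processing are out of scope.
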