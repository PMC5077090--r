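# specbind

Spectroscopic titration analysis for protein–ligand and
protein–nanoparticle interactions.

When a ligand quenches a protein's intrinsic tryptophan fluorescence, a
handful of classical linear analyses turn a stack of instrument scans into
the numbers that characterise the interaction:

- **Stern–Volmer quenching** — F₀/F = 1 + K_SV·[Q]. The bimolecular rate
  k_q = K_SV/τ₀ (τ₀ ≈ 6 ns for tryptophan) separates static quenching
  (ground-state complex, k_q far above the ~10¹⁰ M⁻¹s⁻¹ diffusion limit)
  from dynamic, collisional quenching. Curved plots are handled with two
  independent regimes split at a breakpoint concentration.
- **Double-logarithmic binding isotherm** —
  log₁₀((F₀−F)/F) = log₁₀K_b + n·log₁₀[Q], giving the binding constant K_b
  and the number of binding sites n per protein.
- **van't Hoff thermodynamics** — ln K_b = −ΔH°/(RT) + ΔS°/R fitted across
  temperatures, ΔG° = ΔH° − TΔS° (Gibbs–Helmholtz), and the sign-based
  (Ross–Subramanian) classification of the dominant forces: both negative →
  hydrogen bonds / van der Waals; both positive → hydrophobic; ΔH° < 0,
  ΔS° > 0 → electrostatic.
- **Conformational probes** — synchronous-fluorescence λ_max shifts
  (Δλ = 15 nm for Tyr, 60 nm for Trp; a red shift signals solvent
  exposure), ANS extrinsic-probe normalisation with saturation-plateau
  detection, first-derivative melting temperatures from thermal scans,
  circular-dichroism mean residue ellipticity
  MRE = Θ/(10·C_p·n·l) with α-helix% = (−MRE₂₀₈ − 4000)/29000 × 100,
  and the zeta-potential colloidal-stability rule (>30 mV good, 5–30 mV
  short-term, <5 mV fast aggregation).

Every analysis takes a data frame and returns a tibble or a small fit
object with `tidy()`/`glance()`/`autoplot()` methods, so the pieces chain
with the pipe. A seeded synthetic-data generator (`ground_truth()` +
`generate_*()`) emulates every instrument input with known parameters, and
`run_pipeline()` assembles the full workflow into one machine-readable
report (`report_json()`).

## Worked example

Simulate a two-regime quenching titration (1% instrument noise), extract
the quenching points and fit:

```r
library(specbind)

truth <- ground_truth()   # K_SV = 29.25e3 / 3.492e3 1/M, breakpoint 15 uM
titr  <- generate_titration(truth, model = "sv_two_regime",
                            rel_sigma = 0.01, seed = 42)
fit <- titr |> stern_volmer_points() |> fit_two_regime_sv(breakpoint = 15e-6)
fit
#> Stern-Volmer fit (7 points, breakpoint 1.5e-05 M)
#> # A tibble: 2 x 11
#>   regime      kq intercept_dev  conc_lo conc_hi n_points   K_SV stderr ...
#> 1      1 4.91e12     -0.000854 0         1.5e-5        4 29434.   44.7
#> 2      2 5.83e11      0.385    0.000015  1  e-4        3  3501.   20.4
classify_quenching(fit)$mechanism
#> [1] "mixed_static_then_dynamic"
```

The fitted slopes recover the generator's constants within noise
(29 434 vs 29 250 M⁻¹; 3 501 vs 3 492 M⁻¹), and the regime rates
k_q ≈ 4.9×10¹² and 5.8×10¹¹ M⁻¹s⁻¹ classify the quenching as static at low
concentration followed by dynamic collisional quenching above the
breakpoint.

Thermodynamics from binding constants measured at three temperatures:

```r
kb <- tibble::tibble(temperature_K = c(298, 310, 315),
                     Kb = c(105.07, 45.42, 7.52))
thermo_profile(kb)
#> Thermodynamic profile: dH = -107.9 kJ/mol, dS = -321.8 J/(mol K), hbond_vdw
#>   temperature_K      dG spontaneous
#> 1           298 -11995. TRUE
#> 2           310  -8133. TRUE
#> 3           315  -6524. TRUE
```

Binding is exothermic, entropically unfavourable, spontaneous at every
temperature, and sign-classified as hydrogen-bond / van der Waals driven.
`vant_hoff_consistency()` compares a fit against externally quoted ΔH°/ΔS°
and warns when they cannot have come from the same OLS fit.

A melting temperature from a simulated thermal scan:

```r
mc <- generate_melting_curve(ground_truth(melting = list(Tm = 65.48)),
                             rel_sigma = 0.01, seed = 1)
melting_tm(mc)
#> First-derivative melting temperature: Tm = 65.42 C
```

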