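# ndcrate

Golden-rule rates for nonadiabatic transitions driven by derivative couplings.

## The problem

When two electronic states of a molecule are coupled by the nuclear-momentum
(derivative-coupling) operator rather than by a constant diabatic coupling —
the generic situation for internal conversion between adiabatic states — the
Fermi golden-rule rate is no longer a bare Franck–Condon-weighted density of
states. For a bath of displaced harmonic oscillators (mode frequencies
ω<sub>j</sub>, vibronic couplings g<sub>j</sub> with Huang–Rhys factors
g<sub>j</sub>², and signed derivative-coupling projections f<sub>j</sub>),
the rate becomes a time-domain integral

```
k = (1/ħ²) 2 Re ∫₀^∞ dt  e^{i(Δ−λ)t/ħ} e^{−g(t)} [ D(t) + F(t)² ]
```

where Δ is the adiabatic (0–0) energy gap, λ the total reorganization
energy, g(t) the usual lineshape exponent, and two additional bath kernels
carry the non-Condon momentum physics:

```
g(t) = Σⱼ gⱼ² [ coth(βħωⱼ/2)(1−cos ωⱼt) + i(sin ωⱼt − ωⱼt) ]
F(t) = Σⱼ (ħωⱼ gⱼ fⱼ/√2) [ coth(βħωⱼ/2)(1−cos ωⱼt) + i sin ωⱼt ]
D(t) = Σⱼ (ħωⱼ)² fⱼ²/2  [ coth(βħωⱼ/2) cos ωⱼt − i sin ωⱼt ]
```

Equivalently, three bath spectral densities are needed: the conventional
Franck–Condon density J(ω), a squared-NDC density J_D(ω), and a signed
cross density J_F(ω). The Condon reference rate freezes the non-Condon
bracket at its t = 0 value, D(0) (F(0) vanishes identically). These kernel
formulas are validated in the test suite against a numerically exact
truncated-Fock-space computation of the full correlation function.

The package is for theoretical/computational chemists who want to compute
such rates from either (a) the analytically solvable Ohmic-plus-delta bath
family, (b) discrete normal-mode tables (e.g. distilled from quantum
chemistry), optionally broadened by a normalized Brownian-oscillator
lineshape, or (c) tabulated spectral densities.

## What's inside

* **Bath models** — `ohmic_delta_params()`, `discrete_modes()`,
  `triple_from_modes()` (with optional Brownian-oscillator `gamma`),
  `bo_lineshape()`, `check_cross_bound()` (the |F_l| ≤ D_l/2 and
  Cauchy–Schwarz constraints), `reorganization_energy()`.
* **Correlation functions** — closed forms for the Ohmic+delta family
  (`corr_closed_form()`, exact thermal sums with a closed-form tail, plus an
  optional interpolation approximation), spectral quadrature
  (`corr_from_spectrum()`) with analytic handling of delta components, and
  exact discrete-mode sums (`corr_from_discrete()`). All three paths agree
  to the documented tolerances.
* **Rates** — `fgr_rate()` (with Condon reference, Richardson and
  imaginary-residual diagnostics), `gap_scan()`, `assemble_integrand()`.
* **Fixtures** — the six named reduced-unit model cases (`table2_case()`),
  seeded `random_modeset()`, and a synthetic azulene-like 48-mode surrogate
  (`azulene_surrogate()`) with five environmental bath settings
  (`surrogate_bath_settings()`).
* **I/O + CLI** — delimited-text tables with reproducing metadata headers,
  YAML run configurations, and a thin command line (`inst/cli/ndcrate`) with
  subcommands `spectra | corr | rate | scan | fixtures`.

## Worked example

Reduced units (k_B = ħ = ω_c = 1), model case I-A — a single high-frequency
mode at ω_h = 5ω_c carrying all of the derivative coupling on top of an
Ohmic bath, at θ = βħω_c = 1:

```r
library(ndcrate)
case <- table2_case("I-A")
corr <- corr_closed_form(case$params, case$thermo, time_grid(60, n = 3000))
fgr_rate(corr, gap = 20)      # gap in units of hbar*omega_c
#> <ndc_rate> gap = 20: k = 11.9485 omega_c (Condon 1.50398)
#>   tail 1.34e-78 | Richardson 1.36e-06 | imag residual 0 | converged: TRUE
```

The full rate (11.9 in ω_c units) exceeds the Condon reference (1.50) by a
factor of ≈ 8: at a gap of 20 ħω_c the momentum terms contribute
high-frequency spectral weight that plain Condon coupling cannot, the
non-Condon enhancement the rate expression was built to capture.

Physical units, the azulene-like surrogate with every mode broadened by a
Brownian-oscillator friction of 400 cm⁻¹ at 300 K (environment setting D):

```r
sur <- azulene_surrogate()
corr <- corr_from_spectrum(triple_from_modes(sur$modes, gamma = 400),
                           thermo_state(300), time_grid(0.6, n = 2000))
fgr_rate(corr, 1.7816, gap_units = "ev", tail_tol = 3e-3)
#> <ndc_rate> gap = 1.7816: k = 0.00189169 ps^-1 (Condon 6.50054e-05)
#>   = 1.89169 ns^-1 (Condon 0.0650054 ns^-1)
#>   tail 1.01e-54 | Richardson 2.51e-05 | imag residual 0 | converged: TRUE
```

A nonradiative decay rate of ≈ 1.9 ns⁻¹ at the lower edge of the
experimental gap window — orders of magnitude slower than the observed
picosecond decay, consistent with direct derivative-coupling decay not being
the dominant channel for this system.

From the shell:

```sh
Rscript inst/cli/ndcrate fixtures --out out/           # emit mode table + case configs
Rscript inst/cli/ndcrate scan --config out/ndcrate_case_I-A.yaml --out out/run
```

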