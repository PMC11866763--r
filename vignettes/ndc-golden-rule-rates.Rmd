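---
title: "Momentum-coupled golden-rule rates: model, conventions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Momentum-coupled golden-rule rates: model, conventions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndcrate)
```

## The model

`ndcrate` computes Fermi golden-rule rates for a transition between two
electronic states whose coupling operator is linear in the nuclear momenta
(a derivative coupling), with all nuclear and environmental degrees of
freedom represented as displaced harmonic oscillators: mode frequencies
$\omega_j$, dimensionless vibronic couplings $g_j$ (Huang–Rhys factors
$g_j^2$, total reorganization energy
$\lambda = \sum_j \hbar\omega_j g_j^2$), and signed dimensionless
derivative-coupling projections $f_j$ that carry the purely imaginary
momentum coupling $i f_j$ per mode. The two surfaces share frequencies and
differ by displacements only — no Duschinsky rotation, no frequency changes,
no anharmonicity.

For this Hamiltonian the golden-rule rate has a closed form in the time
domain,

$$
k \;=\; \frac{1}{\hbar^2}\, 2\,\mathrm{Re}\!\int_0^{t_{\max}}\! dt\;
e^{\,i(\Delta-\lambda)t/\hbar}\; e^{-g(t)}\,\bigl[\,D(t) + F(t)^2\,\bigr],
$$

with the three bath kernels

$$
\begin{aligned}
g(t) &= \sum_j g_j^2\bigl[\coth(\beta\hbar\omega_j/2)(1-\cos\omega_j t)
        + i(\sin\omega_j t - \omega_j t)\bigr],\\
F(t) &= \sum_j \tfrac{\hbar\omega_j g_j f_j}{\sqrt2}
        \bigl[\coth(\beta\hbar\omega_j/2)(1-\cos\omega_j t) + i\sin\omega_j t\bigr],\\
D(t) &= \sum_j \tfrac{(\hbar\omega_j)^2 f_j^2}{2}
        \bigl[\coth(\beta\hbar\omega_j/2)\cos\omega_j t - i\sin\omega_j t\bigr].
\end{aligned}
$$

$D(t)$ is the momentum–momentum kernel; $F(t)$ is the cross kernel between
momentum coupling and vibronic displacement and enters squared; $F(0)=0$
identically, so the *Condon reference rate* — the same integral with the
bracket frozen at $t=0$ — uses the effective coupling $D(0)$ alone. The
bracket structure $e^{-g}[D+F^2]$, including the relative signs of
mixed-sign $f_j$, is pinned in the test suite by an independent, numerically
exact truncated-Fock-space evaluation of the full correlation function
(`tests/testthat/helper-oracles.R`); this oracle, not any internal formula,
is the package's ground truth.

### Spectral densities and strength conventions

For continuum baths the kernels become integrals over three spectral
densities, carried internally as angular-frequency densities

$$
J(\omega) = \pi\sum_j \omega_j^2 g_j^2\,\delta(\omega-\omega_j),\qquad
J_D: g_j^2 \to f_j^2,\qquad
J_F: g_j^2 \to g_j f_j .
$$

Every "strength" is the same functional,
$\tfrac1\pi\int_0^\infty J_X(\omega)/\omega\, d\omega$, which makes the
parameter mappings of the Ohmic-plus-delta family exact by construction:
the family is

$$
J(\omega) = \pi\eta\,\omega e^{-\omega/\omega_c}
 + \pi s_h \omega_h^2\,\delta(\omega-\omega_h),
$$

(and analogously $\eta_D, s_D$ for $J_D$, signed $\eta_F, s_F$ for $J_F$),
so that $\lambda_l = \eta\hbar\omega_c$, $\lambda_h = s_h\hbar\omega_h$,
$D_l = \eta_D\hbar\omega_c$, $D_h = s_D\hbar\omega_h$,
$F_l=\eta_F\hbar\omega_c$, $F_h = s_F\hbar\omega_h$ hold identically. The
$\omega e^{-\omega/\omega_c}$ convention also places the Ohmic maximum at
exactly $\omega_c$. Constraints: the delta components originate from one
physical mode, hence $s_F^2 = s_h s_D$ (sign free); the Ohmic cross
component is bounded, $|\eta_F| \le \eta_D/2$. `check_cross_bound()`
enforces the parametric bound and, for microscopic (discrete or broadened)
baths, the pointwise Cauchy–Schwarz consistency
$J_F^2 \le J\,J_D$, which a per-mode construction saturates and can never
violate.

Delta components are **never discretized onto frequency grids**: they are
carried as tagged point masses and summed analytically in every downstream
integral.

### The energy gap convention

The package's `gap` argument $\Delta$ is the **adiabatic (minimum-to-minimum,
0–0) energy gap**, the quantity quoted by experiment. The phase factor of
the rate integral is therefore $e^{i(\Delta-\lambda)t/\hbar}$, with
$\lambda$ carried by the correlation set; this is algebraically identical to
formulations whose electronic gap absorbs the reorganization shift. Two
consequences worth knowing: the classical stationary-phase limit gives the
Marcus form $\exp[-(\Delta-\lambda)^2/4\lambda k_BT]$ in terms of the
driving force $\Delta$, and the Condon reference obeys detailed balance
exactly as $k(\Delta)/k(-\Delta) = e^{\beta\Delta}$. Both are verified
numerically in the acceptance tests. Small or negative gaps are accepted but
are outside the regime where the underlying quasi-adiabatic treatment of
the coupling is well justified.

### Units

Internally every energy-like quantity is an angular frequency (rad/ps) and
time is in ps, so $\hbar$ never appears explicitly and the hbar-scaled
kernels $F/\hbar$ (ps⁻¹) and $D/\hbar^2$ (ps⁻²) — the quantities exported by
`write_corr()` — fall out directly, as do rates in ps⁻¹. User-facing inputs
are cm⁻¹ (or eV for gaps); a reduced-unit mode sets
$k_B=\hbar=\omega_c=1$ with the single thermal parameter
$\theta = \beta\hbar\omega_c$ (`thermo_state(theta = ...)`).

## Evaluation paths

Three independent routes produce the kernels; their mutual agreement is a
standing regression target.

**Closed forms (Ohmic + delta).** Expanding
$\coth(\beta\hbar\omega/2) = 1 + 2\sum_{n\ge1}e^{-n\beta\hbar\omega}$ and
integrating termwise gives thermal sums over
$\tau_n = \omega_c t/(1+n\theta)$, e.g.
$\mathrm{Re}\,g_l = \eta[\tfrac12\ln(1+\tau_0^2) + \sum_{n\ge1}\ln(1+\tau_n^2)]$
and $\mathrm{Im}\,g_l = \eta[\arctan\tau_0 - \tau_0]$ (the $-\tau_0$ drift
is the reorganization phase: $\mathrm{Im}\,g \to -\lambda_l t/\hbar$ at long
times). The sums converge like $n^{-2}$, so they are evaluated as `n_exact`
direct terms (default 4000) plus a **closed-form Euler–Maclaurin midpoint
tail**: substituting $u=\tau_n$ turns the tail into elementary integrals
($\int\ln(1+u^2)/u^2$ via the arctangent, $\int(1-u^2)/(1+u^2)^2$,
$\int u/(1+u^2)$), giving ~1e-10 relative accuracy at modest cost.
With `use_eq_approx = TRUE` the same closure is applied after only two
direct terms — an interpolation-style approximation built on the arctangent
integral whose deviation from the exact sums is below 2% for
$\theta\approx1$ (tested); the exact sum is always the default and the
ground truth.

**Spectral quadrature.** Continuous densities are converted to point masses
on composite Gauss–Legendre nodes (`pracma::gaussLegendre`), with panel
widths that resolve both the envelope ($\omega_c/4$) and the oscillatory
factor ($\ge 8$ nodes per period of $e^{i\omega t_{\max}}$), and a cutoff
where the exponential envelope is below ~1e-16. The node masses then flow
through the *same* exact summation engine as discrete modes, so delta
components are handled identically on every path. Against the closed forms
this path agrees to better than 1e-6 relative over $t\omega_c \in (0,10]$
for all six built-in model cases (acceptance test); against discrete sums it
is algebraically identical (1e-10 assertion).

**Brownian-oscillator broadening.** Each discrete mode can be replaced by
the normalized lineshape
$J_\gamma(\omega;\omega_j) = A_j\,\gamma\omega/[(\omega^2-\omega_j^2)^2+\gamma^2\omega^2]$,
linear at $\omega\to0^+$ and decaying as $\omega^{-3}$ — the limits that
keep all three kernels finite. The normalization constant $A_j$ is evaluated
in closed form (under-, over- and critically damped branches), not by
runtime quadrature, and unit normalization is verified to <1e-6 by adaptive
quadrature in the tests. For kernel evaluation the lineshape is sampled into
sub-mode masses: windows of ±12γ and ±120γ around each mode with node
spacing below $2\pi/(3t_{\max})$ (so that spurious discretization
recurrences lie beyond the integration window), plus a coarse tail, with
per-mode masses renormalized so broadening conserves integrated weight
exactly. The coarse tail implies an absolute kernel accuracy of order
1e-4·D(0) for heavily broadened baths; its effect on rates is far smaller
because those frequencies lie deep in the Franck–Condon tail.

## Rate integration

The slow part of the integrand, $e^{-g}[D+F^2]$, lives on the correlation
grid; `fgr_rate()` resamples it by cubic spline onto a uniform fine grid
whose spacing resolves the gap phase
($dt \le 2\pi\hbar/[20(|\Delta| + \hbar\omega_{\max})]$, the `per_period`
control) and applies the trapezoidal rule, plus the same integral at half
the spacing as a Richardson consistency check (`richardson_rel`). The
reported diagnostics are honest gates: `integrand_tail` (relative magnitude
of the slow integrand at $t_{\max}$), `richardson_rel`, and
`imag_residual` — the imaginary part of the full two-sided integral,
recomputed by evaluating the kernels at *negative* times through the stored
evaluator rather than by assuming Hermitian symmetry. Converged
configurations change by far less than 0.1% under dt-halving or
$t_{\max}$-doubling (tested).

Purely discrete baths never dephase: their integrand recurs forever and no
rate exists. `fgr_rate()` and `gap_scan()` refuse them unless either real
broadening is added (Ohmic component or BO $\gamma$) or an explicitly
labelled, physically artificial `gaussian_damping` window is supplied — a
deliberate design choice in favour of window-free rates.

Energy-gap scans reuse one correlation set (the gap enters only through the
phase), flag non-converged points instead of failing, and emit
$\ln k$ directly for progression analysis.

## The built-in model cases and what they show

`table2_case()` returns the six reduced-unit parameter sets used in the
model study ($\omega_h/\omega_c = 5$ or 15; derivative coupling carried by
the high-frequency mode alone in the A cases, Ohmic-dominated with either
cross sign in B/C; $\eta = 1$, $\theta = 1$). The acceptance suite checks
their qualitative physics: non-Condon enhancement growing with the gap,
vibrational-progression maxima spaced by $\omega_h$ within 10%, the
dominance ordering (zeroing $J_F$ perturbs the rate less than zeroing
$J_D$), and the large-gap case ordering $k_\mathrm{I\text{-}A} >
k_\mathrm{I\text{-}B} > k_\mathrm{I\text{-}C}$. One subtlety is documented
here deliberately: with the exact kernels the B-versus-C comparison
oscillates with the progression phase of the high-frequency mode — B exceeds
C on the envelope and at the largest gaps, while individual gap values can
locally invert. The ordering test therefore compares geometric means over
one full progression period centred at a gap of $20\,\hbar\omega_c$, which
is the envelope statement, rather than a single phase-sensitive point.

## The synthetic generator and the surrogate

`random_modeset()` draws log-uniform frequencies and scales couplings so the
reorganization energy and integrated NDC strength match the requested
envelope exactly (to 1e-6), deterministically for a fixed seed; cross
strength is steered by greedy sign flips with an explicit impossibility
error beyond the per-mode bound. All randomness flows through the single
seed argument and the caller's RNG stream is restored afterwards.

`azulene_surrogate()` is a fixed, hand-specified 48-mode set emulating the
qualitative structure reported for azulene's S₁→S₀ transition: derivative
coupling dominated by a single mode at 1924 cm⁻¹, Franck–Condon weight
concentrated below 1600 cm⁻¹, and nearly silent CH stretches near
3050 cm⁻¹. Two calibration choices were made once and frozen: the total
Huang–Rhys activity (λ ≈ 2860 cm⁻¹) is large enough that the
isolated-molecule Franck–Condon envelope dephases within ~0.3 ps — without
this, weakly damped environments never reach a near-intrinsic rate and the
characteristic pattern (weak-Ohmic and weak-BO settings nearly equal and
lowest, broadened settings enhanced) cannot appear; and the overall NDC
scale ($f$-scale 0.035) puts all five environmental settings at rates of
order 0.1–10 ns⁻¹ over the 1.7816–1.8176 eV gap window at 300 K. The
surrogate is synthetic: it reproduces distributional features and trends,
not any published per-mode data or absolute rate, and no such agreement is
claimed or tested. What passing surrogate tests demonstrate is that the
pipeline — mode table → (broadened) spectral triple → kernels → rate scan —
is finite, convergent and trend-correct for a realistically sized molecular
input; they say nothing about the accuracy of any specific ab initio
parameterization of a real molecule.

The five environment settings (`surrogate_bath_settings()`) exercise the two
coupling routes separately and together: an Ohmic bath added to $g(t)$ only
(weak: η=1, ν̃_c=10 cm⁻¹; strong: η=10, ν̃_c=200 cm⁻¹), BO broadening of
every mode (γ̃=10 or 400 cm⁻¹), and the combination.

## Numerical choices, degenerate inputs, limitations

* Thermal-sum truncation and quadrature node densities are accuracy
  controls with conservative defaults (`n_exact`, `per_period`, `tol`);
  all tolerances quoted above are asserted in the test suite, not assumed.
* $t=0$ values are set exactly ($g(0)=F(0)=0$, $D(0)$ real) rather than
  left to summation roundoff. Negative times are never stored; consumers
  reconstruct them via Hermitian symmetry, and the two-sided diagnostic
  re-evaluates them independently.
* Empty mode sets are legal (zero kernels, warning at correlation stage);
  zero coupling yields exactly zero rate with converged diagnostics.
* Problem sizes used by the shipped tests and acceptance script — reduced
  grids of 3000–6000 points, 1.7–10 ps windows with 2000–20000 points for
  the surrogate — were chosen as the smallest sizes at which every
  convergence diagnostic is clean; they are package defaults, and all are
  user-adjustable.
* Out of scope by design: Duschinsky rotation and frequency changes,
  anharmonicity, higher-order (non-golden-rule) corrections, conical
  intersection dynamics, spectra, and any fitting of spectral densities to
  simulation time series (tabulated densities are accepted as-is via
  `triple_from_table()`).
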