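---
title: "A fractional-order tumor-immune treatment model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fractional-order tumor-immune treatment model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`fotsim` integrates a 15-compartment compartmental model of treated breast
cancer. The state vector is

`y = [N1, N2, I1, I2, P, A, Q, R1, R2, S, D, Dm, G, M, H]`

with sensitive (`N1`) and partially resistant (`N2`) cycling tumor cells,
cytotoxic (`I1`) and regulatory (`I2`) immune cells, metastatic potential
`P`, angiogenic factor `A`, quiescent cells `Q`, two resistant
subpopulations `R1`/`R2`, senescent cells `S`, drug concentration `D` and
metabolized drug `Dm`, a 0-1 genetic-stability index `G`, a metabolic
status `M` and a hypoxia level `H`. Time is measured in days everywhere;
the 24-hour circadian period is stored internally as 1 day.

The fluxes are built from shared intermediates. Total burden
`T = N1 + N2 + Q + R1 + R2 + S` drives a logistic factor
`max(0, 1 - T/K)` with shared carrying capacity `K`; growth of each
cycling population is the compartment's rate times
`ccf * (1 + 0.2 M) / (1 + acidosis_factor * M * T/K)`, so metabolic
activation boosts growth while metabolically produced acid depresses it.
Hypoxia is burden-driven,
`hf = max(0, T/K - hypoxia_threshold) / (1 - hypoxia_threshold)`, and
impairs immune killing through `1 / (1 + 0.5 hf)`, promotes quiescence
through `1 + 0.5 hf`, slows quiescence exit by the same factor, shifts
metabolism (`M' = M * hf * metabolic_switch_rate - 0.05 M`) and damages
the genome. Immune killing is a mass-action term
`beta1 * X * I1 / (1 + 0.01 T)` with population-specific susceptibility
(1 for `N1`, 0.5 for `N2`, `immune_resist_factor1/2` for `R1`/`R2`).
Therapy enters as a linear combination
`therapy_effect = eta_E uE + eta_H uH + eta_C uC`, which kills `N1` (and
`N2` at half strength), induces senescence, and — scaled by
`omega_R1/omega_R2`, the protocol resistance multiplier and the
instability factor `1 + (1 - G)` — converts sensitive cells into the two
resistant pools. Immunotherapy `uI` boosts cytotoxic and suppresses
regulatory cells (`±0.1 uI`) and multiplies the kill terms by
`immuno_boost = 1 + immuno_resist_boost * uI`. Drug mass moves
conservatively from `D` to `Dm` at the organ-function-adjusted
elimination rate.

### Memory scaling

The fractional-order character is a time-dependent factor multiplying the
entire right-hand side:

`gamma(t, alpha) = 0.01 (1 + (1 - alpha) min(t^(-alpha), 100))` for
`t > 0`, and 1 at `t = 0`.

At `alpha = 1` the factor is the constant 0.01 — a uniform slowing of the
nominal daily rates — and for `alpha < 1` a power-law decaying boost makes
early dynamics faster, emulating history dependence. This is an explicit
surrogate: it reproduces the power-law time scaling of fractional systems
without integrating a Caputo memory kernel over the trajectory history. A
genuine fractional solver is a possible extension, deliberately out of
scope here; conclusions about "memory" therefore concern this surrogate
only. The factor's jump at `t = 0` (1 to roughly 0.26 at `t = 1e-9` for
`alpha = 0.75`) is handled by starting integration at `t = 1e-9`; the
`t = 0` output sample reports the initial state.

### Circadian modulation

With `circadian_enabled` (the default), the unit-period sine
`1 + 0.2 sin(2 pi t)` modulates exactly four rates: `lambda1`, `lambda2`,
`delta_I` and `beta1`. Because the amplitude must stay below 1, validation
rejects `circadian_amplitude >= 1`.

## Parameters

The 58 named parameters carry their baseline values and an evidence
category — 11 experimental, 21 clinical, 19 literature-based, 7
hypothetical — and serialize to flat YAML with a category sidecar
(`inst/extdata/parameters/baseline.yaml`). Rates are per day;
`K` (carrying capacity, 1000 cell units), `ec50` (0.3, concentration
units) and doses are dimensionless model units; `distribution_vol` is in
liters. Several tabulated parameters (`epigenetic_silencing`,
`bmi_factor`, `age_factor`, `performance_status`,
`prior_treatment_factor`, `microenv_stress_factor`,
`treatment_cycle_period`, `treatment_active_days`, `rest_period_days`,
`treatment_intensity`) appear in no printed flux; they are stored,
validated and documented as inert rather than silently wired into
invented equations. The hypoxia effect `1 + hf * A / (1 + A)` is likewise
computed and reported among the intermediates but not connected to any
flux by default (`model_options(use_hypoxia_effect = TRUE)` multiplies
the growth terms by it for exploration).

Patient profiles replace `mutation_rate` and `genetic_instability`, store
the organ-function factors (which act through the adjusted elimination
rate `elimination_rate * liver_function * kidney_function`), and scale
immune production `phi1`, `phi2` by `immune_status`. We scale production
rather than the kill rate `beta1` because the kill rate is an
experimentally anchored cytotoxicity constant while production reflects
host immune competence; the mapping is a single documented choice, not a
fitted quantity.

## Controls: why the scheduled dose drives therapy directly

Two readings of the therapy controls are defensible: feed the scheduled
dose into `therapy_effect` directly, or first run it through the
pharmacokinetic compartment and the Hill dose-response
`max_effect * c^h / (ec50^h + c^h)`. Both are implemented
(`model_options(control_mode = ...)`). The default is `"raw_dose"`, for a
structural reason: with the baseline pharmacokinetics the concentration
compartment equilibrates toward `absorption_rate * dose *
bioavailability / (distribution_vol * elimination_rate)` which is about
0.05 — far below the EC50 of 0.3 — so Hill-transformed controls make
`therapy_effect` of order 1e-4 and all five protocols produce practically
identical trajectories. Only the raw-dose reading separates the protocols
(continuous > adaptive > standard > hyperthermia > immuno_combo for the
average patient at `alpha = 0.75`), which is the regime the analysis
tooling is built to study. The Hill machinery remains the documented
dose-response for the drug state itself and for users who rescale the
pharmacokinetics.

Other resolutions of formulation ambiguities, each switchable in
`model_options()`:

* the metastatic seeding term divides by `1 + 0.5 hf` (mirroring the
  quiescence-exit structure); `"multiply"` is available;
* `immuno_boost = 1 + immuno_resist_boost * uI`, a linear boost anchored
  at 1 when no immunotherapy is on board;
* hyperthermia multiplies `therapy_effect` by
  `1 + 0.1 (T_degC - 37)` during sessions (`hyperthermia_coef`
  configurable, 0 disables). The coefficient is an artifact choice — the
  protocol defines the temperature schedule but no thermal-effect
  equation.

## Protocols and the adaptive controller

The five bundled protocols: standard (hormone + HER2, 14 d on / 7 d off,
dose 0.8), continuous (same drugs, no rest, 0.8), adaptive (dose in
[0.6, 0.9]), immuno_combo (chemo 0.6 at 7/14 plus immunotherapy 0.7 at
2/19) and hyperthermia (0.7 at 14/7 plus 38.5 °C for 2 days every 21).
Continuous and adaptive carry the resistance-development multipliers 2.0
and 1.2 on `omega_R1/omega_R2`.

The adaptive controller reviews the tumor burden every
`monitoring_period = 21` days: if `burden(t)/burden(t - 21)` exceeds
`target_ratio = 1`, the dose steps up by 0.1 (capped at 0.9); below the
reciprocal it steps down (floored at 0.6); otherwise it holds. The
initial dose is 0.75, the midpoint of the band. Monitoring period, step
and initial dose have no stated values in the source tables; these
defaults are documented and configurable and were fixed once.

## Numerical choices

* **Nonnegativity floor.** Every derivative evaluation clamps its incoming
  state copy at 1e-6 (`G` additionally to at most 1, since its recovery
  term targets 1 and the index is defined on [0, 1]). The floor lives
  inside the right-hand side — not as post-hoc trajectory clipping — so
  the ODE stays well defined; reported trajectories are additionally
  clamped at 1e-6 so the floor invariant holds sample-wise.
* **Solver chain.** `safe_solve` tries RK45, BDF, Radau, then LSODA
  (`deSolve` methods `ode45`, `bdf`, `radau`, `lsoda`; the chain's
  explicit 8th-order member has no `deSolve` equivalent, so LSODA closes
  the ladder), each at the configured tolerances and once more at 10x
  relaxed tolerances, before returning a flagged dummy result. Defaults
  `rtol = 1e-4`, `atol = 1e-7`, 501 daily samples over 500 days.
* **Per-drug compartments.** Each protocol drug gets an internal
  concentration compartment; `D` is their sum, so the aggregate
  drug-mass-balance `d(D + Dm)/dt = 0` holds under zero input. Both the
  `D` sink and the `Dm` source use the organ-adjusted elimination rate,
  keeping the balance exact for every patient profile.
* **Adaptive protocols** integrate piecewise between controller reviews;
  dose changes occur only at monitoring boundaries, which the tests
  assert.
* **Reference integrator.** A hand-rolled fixed-step classical RK4
  (`reference_integrate`) shares the exact right-hand side and serves as
  the cross-check oracle; at `rtol = 1e-8` the adaptive solver agrees
  with it to better than 1e-3 relative over 10 days.
* **Tie-breaks.** Protocol rankings order by efficacy, then higher tumor
  reduction, then protocol name. Variability tables use the sample
  standard deviation (n - 1). Sensitivity classes use closed lower
  boundaries (`s_max = 1.0` is critical, `0.5` important).

## Sensitivity engine

The local analysis perturbs each parameter multiplicatively at -20%,
-10%, +10%, +20% around its profile-adjusted baseline in each of the 20
profile x protocol contexts (4,640 runs for the full 58-parameter
design) and computes `S = (dO/O_baseline) / (dp/p_baseline)` for the
three outcome metrics. Per parameter, the ranking statistic is the
maximum `|S|` over levels and contexts on the efficacy score. The
fractional order itself is excluded from perturbation and defaults to
`alpha = 1` (the memoryless reference) for sensitivity runs, since the
study design treats memory strength as an experimental axis, not a
biological parameter. Records from non-converged runs are dropped and
counted; the engine warns when retention does not exceed 95%. Injecting
a closed-form response in place of the simulator (the `simulator`
argument) recovers exact elasticities, which the tests use as the
engine's oracle.

## What the default conditions emulate — and what they do not

The default configuration is the study's reference condition: 500
simulated days, daily sampling, initial state
`N1 = 190, N2 = 10, I1 = 40, I2 = 10, P = 0.1, A = 1, Q = 0.1,
R1 = R2 = 1, S = 0.1, D = Dm = 0, G = M = 1, H = 0` (initial burden
202.2), circadian modulation on, and the seven fractional orders 0.75,
0.80, 0.85, 0.90, 0.93, 0.95, 1.00. Under these conditions treatment
outcomes are dominated by immune clearance with therapy contributing a
protocol-dependent increment — which is why the efficacy scores of all
protocols cluster around 28-32 and why the immune kill rate is the most
sensitive parameter. These are deterministic, spatially homogeneous,
single-lesion dynamics in arbitrary cell units: no stochastic extinction,
no spatial drug gradients, no inter-patient variability beyond the four
discrete profiles, and no pharmacodynamic interaction between drugs.
Passing tests demonstrate internal consistency and reproduction of the
reference computational study, not clinical validity.

Problem sizes used by the test-suite: the right-hand-side equivalence
property uses 1,000 random state/parameter draws; solver cross-checks run
10-day horizons; floor/bounds properties run the full 500-day reference
configuration; the ranking reproduction runs the 35-configuration
average-patient slice of the grid; and the sensitivity reproduction runs
the 80-perturbation single-parameter design for `beta1`. The full
140-run grid and 4,640-run design are exercised through their
enumerations plus representative slices, keeping the default suite a
few minutes long.

## Known limitations

* The memory factor is a surrogate, not a Caputo integrator; `alpha`
  sweeps probe the surrogate's power-law scaling only. In particular the
  model's efficacy response to `alpha` is a smooth trend of a few tenths
  of an efficacy point for the continuous protocol (the acceptance script
  computes it), considerably smaller than tolerance-level scatter can
  appear under loose solver settings.
* Six tabulated parameters are inert by design (no governing printed
  flux); perturbing them yields zero sensitivity.
* `resistance_floor` acts only at initialization (the printed dynamics
  contain no floor term).
* The controller reviews burden on the daily output grid; sub-daily
  monitoring would require a finer grid.
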