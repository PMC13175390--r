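# fotsim — fractional-order tumor–immune treatment simulation

`fotsim` simulates breast-cancer treatment with a 15-compartment ordinary
differential equation model of tumor growth, immune interaction, resistance
evolution, quiescence/senescence, the tumor microenvironment and drug
pharmacokinetics, in which the entire derivative vector is scaled by a
time-dependent *fractional-order memory factor*

```
gamma(t, alpha) = 0.01 * (1 + (1 - alpha) * min(t^(-alpha), 100)),  t > 0
```

with `gamma = 1` at `t = 0`. The fractional order `alpha` in (0, 1] acts as
a memory-strength knob: `alpha = 1` is the memoryless classical case, and
smaller values add a power-law decaying boost that makes early dynamics
faster — a surrogate for history dependence (epigenetic persistence, immune
priming, microenvironmental conditioning) without a full Caputo-kernel
integrator.

The package is aimed at modelers who want to stress-test how memory
strength, patient characteristics and dosing strategy interact: it bundles

* the 15-equation model core with circadian modulation of growth, immune
  kill and immune death rates;
* dosing schedulers — cyclic, continuous, response-adaptive (burden-ratio
  controller with dose bounds) and periodic hyperthermia sessions — plus
  Hill-equation pharmacodynamics;
* four virtual patient profiles (average, young, elderly, compromised) and
  five treatment protocols (standard, continuous, adaptive, immuno_combo,
  hyperthermia), with the profile and protocol definitions bundled
  bit-exactly as YAML files;
* a robust solver front-end (`safe_solve`) over `deSolve` with a
  RK45 → BDF → Radau → LSODA fallback chain, tolerance relaxation, a 1e-6
  nonnegativity floor inside the right-hand side, and flagged dummy results
  instead of crashes;
* outcome metrics — percent tumor reduction, final resistant fraction, and
  the composite efficacy score `reduction / (1 + resistance/100)` — with a
  140-run comparative grid (7 fractional orders × 4 profiles × 5
  protocols), protocol rankings, fractional-vs-integer comparisons, and a
  4,640-run one-at-a-time normalized local sensitivity engine
  (`S = (dO/O) / (dp/p)`) with critical/important/non-critical
  classification.

## Worked example

Continuous hormone + HER2 therapy for an average patient under strong
memory effects (`alpha = 0.75`), 500 days with daily sampling:

```r
library(fotsim)

params   <- apply_profile(default_parameters(), "average")
protocol <- treatment_protocol("continuous", params = params)
config   <- simulation_config(duration = 500, n_points = 501, alpha = 0.75)

res <- safe_solve(config, params, protocol)
outcome_metrics(res)
#> tumor reduction: 32.49% (burden 202.20 -> 136.50)
#> resistance fraction: 1.60%
#> efficacy score: 31.98
```

The tumor shrinks from the initial 202.2-unit burden by 32.5%; 1.6% of the
remaining tumor consists of the two resistant subpopulations, discounting
the composite efficacy score to 31.98. Ranking all five protocols for this
patient at `alpha = 0.75` puts continuous therapy first and the
chemo/immunotherapy combination last:

```r
grid <- run_grid(alphas = 0.75, profiles = "average", config = config)
rank_protocols(grid, alpha = 0.75)[, c("rank", "protocol", "efficacy_score")]
#>   rank     protocol efficacy_score
#> 1    1   continuous       31.98041
#> 2    2     adaptive       30.76405
#> 3    3     standard       30.16184
#> 4    4 hyperthermia       29.74955
#> 5    5 immuno_combo       28.15799
```

A command-line wrapper is installed at `inst/cli/fotsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fotsim.R", package="fotsim"))')" \
    simulate --alpha 0.75 --protocol continuous --profile average --out run1
```

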