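# rubberband

Constrained fitting of ODE kinetic models with class-weighted "rubber band"
penalties on parameter deviations, and ranking of competing model variants by
**model plausibility**. The method is demonstrated end to end on a reduced
ammonium transport/assimilation network with two rival transport mechanisms
(active, electrogenic NH₄⁺ uniport vs. passive NH₃ facilitation) fitted to
synthetic training data.

## The idea

Most parameters of a cellular kinetic model are only roughly known. Instead of
minimizing the data misfit and letting poorly known parameters drift anywhere,
this package turns the problem around:

**Objective — stay close to prior knowledge.** Every parameter `p_i` has a
reference value `p_i*` and an uncertainty class; the objective is the weighted
sum of squared log-deviations

```
f(p) = Σ_c λ_c Σ_{i ∈ c} ( ln(p_i / p_i*) )²
```

with λ_I = 1.0407 (measured), λ_II = 0.1930 (educated guess),
λ_III = 0 (rough guess). Tight rubber bands hold measured parameters near
their references; rough guesses move freely. A fourth class, `US`, is fixed
and not searched.

**Constraints — reproduce the data.** Each training set enters as an
inequality on the mean squared relative simulation error:

```
g_i(p) = (1/n) Σ_j ( (x_sim_j − x_exp_j) / x_exp_j )² − ε_i²  ≤  0
```

A parameter set is *feasible* when all `g_i ≤ 0`; total infeasibility is
`γ = Σ max(0, g_i)²`.

**Ranking — plausibility.** The fitted objective maps to the model
plausibility `MP = exp(−f)` (for example `MP(8.4) ≈ 2.2e−4`,
`MP(13.3) ≈ 1.7e−6`, a ratio of about 130). Among variants that all fit the
data, the most plausible is the one whose parameters had to be distorted
least. Replicate optimization runs of two variants are compared with an
exact Wilcoxon rank-sum test on their `f` values.

The constrained search is a real-coded genetic algorithm in log₁₀ parameter
space: JGG generation alternation, REX crossover with an optional
rank-weighted "star" base, stochastic ranking (P_f = 0.45) to trade
feasibility against objective, reflection repair at the box bounds, and
iterative restarts on stalls.

## The demonstration model

A three-state ODE caricature of enterobacterial ammonium handling:
total internal ammonium `nhx` (speciated into NH₄⁺/NH₃ at pKₐ 9.25),
glutamine `gln`, and a downstream pool `glu`. Fluxes: AmtB transport
(throttled by a GlnK Hill term in internal NH₄⁺), passive membrane NH₃
diffusion, Michaelis–Menten assimilation, and glutamine-dependent growth.

The two transport physics differ only in their equilibrium accumulation
factor φ = NH₄⁺_int / NH₄⁺_ext at zero flux:

* active uniport: `φ = exp(−FΔψ/RT)` → **275** at −150 mV / 310 K,
  **313** at 303 K;
* passive NH₃ facilitation: `φ = 10^(pH_ext − pH_int)` → **0.25** at
  pH 7.0/7.6, **0.63** at 7.4/7.6.

Removing GlnK (`glnk_knockout()`) reproduces the classic in-silico futile
cycle: uncontrolled uptake, massive internal accumulation, and outward NH₃
back-diffusion whose proton cost is expressed in ATP equivalents
(1 H⁺ per NH₃ re-imported, 3 H⁺ per ATP).

## Worked example

### 1. Parameter recovery from synthetic data

`default_scenario(seed = 42)` builds a study with known ground truth:
references drawn around the truth with class-dependent spread, observations
(an N-upshift time course, a low-ammonium steady state, a GlnK-knockout
steady state; 8 constraint sets) with 3 % multiplicative noise.

```r
library(rubberband)
real <- realize_scenario(default_scenario(seed = 42))
pr   <- fitting_problem(real$specs, real$constraints, real$conditions)
run  <- ga_optimize(pr, ga_config(length(pr$lower), max_evaluations = 6000,
                                  stall_generations = 120, seed = 1))
```

In ~26 s the GA reaches a feasible fit, `f = 0.0165`, `γ = 0`
(`MP = 0.984`); the noisy references themselves cost `f = 0.0799` at the
truth, so the optimizer recovers a fit *more* plausible than the truth, as
the rubber bands are designed to do. Recovered values:

| parameter | estimate | truth | fold error | class |
|---|---|---|---|---|
| `vmax_amtb` | 234.4 | 150 | 1.56 | II |
| `km_amtb` | 0.00967 | 0.01 | 1.03 | I |
| `p_diff` | 56.6 | 50 | 1.13 | II |
| `vmax_gs` | 5.16 | 5 | 1.03 | II |
| `km_gs` | 0.0211 | 0.02 | 1.05 | I |
| `k_glnk` | 0.0172 | 0.02 | 1.16 | II |
| `mu_max` | 4.14 | 4 | 1.03 | I |
| `k_growth` | 0.998 | 1 | 1.00 | III |

All tightly held class I parameters come back within 6 % of the truth.

### 2. The futile cycle of the GlnK knockout

```r
p    <- toy_params()
cond <- toy_condition("high_n", transport_physics("active"), nhx_ext = 0.1,
                      initial_state = c(nhx = 0.063, gln = 6.4, glu = 69),
                      tau0 = 60)
wt <- steady_state_toy(p, cond)
ko <- steady_state_toy(glnk_knockout(p), cond)
```

At 100 µM external ammonium the wild type throttles AmtB (θ = 0.97,
`v_amtb` = 4.3 mM/min, internal NH₄⁺ 0.11 mM, back-diffusion
−0.095 mM/min). The knockout transports at 29 mM/min, accumulates
21.5 mM NH₄⁺ and loses 24 mM/min of it as outward NH₃ —
`futile_cycle_atp_equivalent(24)` ≈ 8 mM/min ATP burned to pump ammonium
in a circle.

### 3. Ranking the two transport mechanisms

`make_two_model_scenario()` generates one data set from the active-transport
truth and fits *both* variants to it under identical references and
tolerances; `two_model_experiment()` runs five seeded replicates
(GA budgets: 4000 evaluations active, 12000 passive; ~4 min total).

```r
res <- two_model_experiment()
res[, c("seed", "f_active", "f_passive", "mp_ratio", "active_wins")]
```

| seed | f_active | f_passive | MP ratio (active/passive) |
|---|---|---|---|
| 1 | 0.0300 | 9.20 | 9630 |
| 2 | 0.0193 | 3.09 | 21.5 |
| 3 | 0.0302 | 1.90 | 6.51 |
| 4 | 0.0090 | 2.65 | 14.1 |
| 5 | 0.0002 | 2.65 | 14.1 |

Both variants can *fit* the data (γ = 0), but the passive mechanism only by
bending its class II capacities far from their references; the generating
(active) mechanism wins in all five replicates.

## Command-line interface

`inst/cli/rubberband.R` wraps the pipeline for file-based use:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rubberband.R", package = "rubberband"))')
Rscript $CLI synth    scenario.yaml outdir/           # generate a synthetic study
Rscript $CLI fit      specs.csv constraints.csv conddir/ ga.yaml rundir/
Rscript $CLI compare  --a run1,run2 --b run3,run4 --out cmp.json
Rscript $CLI simulate params.csv condition.yaml --t-end 20 --out simdir/
```

Formats: parameter specs CSV (`name,reference,class,lower,upper`),
constraints CSV or YAML, conditions YAML, evaluations JSON; every run writes
a `manifest.json` with input hashes and the seed. Exit codes: 0 success,
2 usage, 3 invalid input, 4 runtime failure. A ready-made scenario file and
fixtures ship in `inst/extdata/`.

## Reproducing results

`scripts/acceptance.R` recomputes the headline quantities (the four
accumulation factors and the two plausibility anchors) with the installed
package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

yielding `t1 = 275`, `t2 = 313`, `t3 = 0.25`, `t4 = 0.63`, `t5 = 2.2e-4`,
`t6 = 1.7e-6`. All six are deterministic closed forms; the seed only fixes
the RNG state for interface uniformity. The stochastic results above are
reproduced exactly by the seeded calls shown in the worked example.

## Further reading

The vignette (`vignettes/rubberband-method.Rmd`) documents the model
equations, parameter table with units and rationale, the optimizer in
detail, what the synthetic generator does and does not emulate, numerical
choices, and limitations.
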