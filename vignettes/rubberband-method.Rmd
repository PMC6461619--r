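---
title: "Constrained kinetic-model fitting with rubber-band penalties and model plausibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained kinetic-model fitting with rubber-band penalties and model plausibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Kinetic models of cellular networks have many parameters, few of which are
known precisely. Classical least-squares fitting treats all parameters as
equally free, which lets poorly constrained rate constants wander to
implausible values whenever that buys a marginally better fit. The method
implemented here inverts the role of the data and the prior knowledge:

* **Prior knowledge is the objective.** Every parameter $p_i$ has a
  *reference value* $p_i^*$ (a measurement, an educated guess, or a rough
  guess) and the objective penalizes the squared log-deviation from it,

  $$ f(p) \;=\; \lambda_\mathrm{I}\sum_{i\in \mathrm{I}}
       \left(\ln\frac{p_i}{p_i^*}\right)^2
     + \lambda_\mathrm{II}\sum_{i\in \mathrm{II}}
       \left(\ln\frac{p_i}{p_i^*}\right)^2
     + \lambda_\mathrm{III}\sum_{i\in \mathrm{III}}
       \left(\ln\frac{p_i}{p_i^*}\right)^2, $$

  with class weights $\lambda_\mathrm{I} = 1.0407 >
  \lambda_\mathrm{II} = 0.1930 > \lambda_\mathrm{III} = 0$ — the "rubber
  bands". A class I (measured) parameter is held tightly, a class II
  (educated guess) loosely, a class III (rough guess) not at all. A fourth
  category, US (*unsearched*), is fixed at its reference and excluded from
  the search.

* **Data are constraints, not the objective.** Each training observation
  set $x^{exp}$ enters as an inequality constraint on the mean squared
  relative error of the simulation,

  $$ g_i(p) \;=\; \frac{1}{n_i}\sum_{j=1}^{n_i}
     \left(\frac{x_j^{sim}(p) - x_j^{exp}}{x_j^{exp}}\right)^2
     - \varepsilon_i^2 \;\le\; 0, $$

  where $\varepsilon_i$ is the allowable relative error of that
  observation set. A parameter vector is *feasible* when every $g_i \le 0$;
  infeasibility is aggregated as
  $\gamma = \sum_i [\max(0, g_i)]^2$.

* **Models are ranked by plausibility.** The fitted objective value maps to
  the *model plausibility* $\mathrm{MP} = e^{-f}$. Among model variants
  that all fit the data ($\gamma = 0$), the most plausible is the one
  whose parameters had to be bent least. Two variants are compared by the
  ratio $\mathrm{MP}_A/\mathrm{MP}_B = e^{f_B - f_A}$ and, across
  replicate optimization runs, by an exact Wilcoxon rank-sum test on the
  per-run $f$ values (`rank_sum_test()`, exact by complete enumeration for
  up to 8 observations per side).

The corresponding primitives are `param_spec()`, `penalty_weights()`,
`objective_f()`, `training_constraint()`, `constraint_residual()`,
`constraint_violation()`, `model_plausibility()` and
`plausibility_ratio()`.

## The optimizer: IS-SR-REX\*/JGG

`ga_optimize()` implements a real-coded genetic algorithm specialized for
this constrained problem. The search runs in $\log_{10}$ parameter space
(`encode_search_vector()`), because parameter values span orders of
magnitude and the penalty acts on log-ratios. Box bounds default to
$\times/\div\,10$, $100$, $1000$ around the reference for classes I, II,
III.

One generation (`jgg_step()`):

1. sample `n_parents` individuals uniformly without replacement
   (*just generation gap*, JGG);
2. produce `n_children` by REX crossover: each child is
   $\mathrm{base} + \sum_i \xi_i (\mathrm{parent}_i - \mathrm{centroid})$
   with $\xi_i \sim N(0,\, e^2/n_\mathrm{parents})$. With the *star*
   option (default) the base is a rank-weighted centroid pulled toward
   better parents; without it, the plain centroid. Out-of-bounds children
   are repaired by reflection (`reflect_bounds()`), not clipping;
3. evaluate the children; any solver failure maps to the sentinel
   $\gamma = +\infty$ (never a silent large number);
4. order the children by *stochastic ranking* (`stochastic_rank()`): a
   probabilistic bubble sort that compares an adjacent pair by $f$ if both
   are feasible or with probability $p_f$ (default 0.45), and by $\gamma$
   otherwise — the standard compromise between chasing feasibility and
   optimizing the objective;
5. replace the sampled parents with the top-ranked children.

An *iterative start* wraps the generations: when the best-so-far
$(\gamma, f)$ pair has not improved by more than 0.1 % (relative) for
`stall_generations` generations, the population is re-initialized at
random while the best individual is kept in an archive. The relative
margin matters: without it, asymptotically vanishing improvements reset
the stall counter on every generation and restarts never fire.

Defaults scale with the search dimension $d$: population $10d$, parents
$d+1$, children $4d$, stall $50d$. Equal seeds give bit-identical runs.

## The demonstration model

`toy_params()` / `toy_rhs()` define a deliberately small ammonium
transport/assimilation network — three states, five fluxes — that keeps
exactly the features the estimation technology is demonstrated on:

* **States** (mM): `nhx` (total internal ammonium, speciated
  algebraically into NH$_4^+$/NH$_3$ by Henderson–Hasselbalch at
  pK$_a$ 9.25), `gln` (glutamine), `glu` (downstream nitrogen pool).
* **AmtB transport** `v_amtb`, in one of two physical variants
  (`transport_physics()`):
  * *active* — electrogenic NH$_4^+$ uniport with equilibrium
    accumulation factor $\varphi = \exp(-F\Delta\psi/RT)$
    (`accumulation_factor_active()`; 275 at $-150$ mV, 310 K), saturable
    in external NH$_4^+$ and driven by $1 - \mathrm{NH_4^{int}}/(\varphi\,
    \mathrm{NH_4^{ext}})$, so the flux vanishes exactly at transporter
    equilibrium;
  * *passive* — NH$_3$ facilitation, $\varphi = 10^{\mathrm{pH_{ext}} -
    \mathrm{pH_{int}}}$ (`accumulation_factor_passive()`; 0.25 at
    pH 7.0/7.6), driven by the NH$_3$ gradient.
* **GlnK regulation**: a Hill function of internal NH$_4^+$
  ($\theta = \mathrm{NH_4}^{n}/(k_\mathrm{glnk}^{n} + \mathrm{NH_4}^{n})$)
  throttles AmtB; `glnk_knockout()` removes it, reproducing the in-silico
  knockout experiment in which uncontrolled uptake plus outward NH$_3$
  back-diffusion form a *futile cycle*. Its energetic cost is
  `futile_cycle_atp_equivalent()`: back-diffusion $\times$ 1 H$^+$/NH$_3$
  $\div$ 3 H$^+$/ATP.
* **Assimilation** `v_gs` (Michaelis–Menten in internal NH$_4^+$),
  **membrane diffusion** `v_diff` $= p_\mathrm{diff}(\mathrm{NH_3^{ext}} -
  \mathrm{NH_3^{int}})$, and **growth** consuming glutamine.

### Parameters, units, defaults

| name | unit | default | class (shipped) | rationale |
|---|---|---|---|---|
| `vmax_amtb` | mM/min | 150 | II | expression-dependent transport capacity |
| `km_amtb` | mM | 0.01 | I | Km-type constant, "measured in vitro" archetype |
| `p_diff` | 1/min | 50 | II | membrane NH$_3$ permeation, order-of-magnitude known |
| `vmax_gs` | mM/min | 5 | II | expression-dependent assimilation capacity |
| `km_gs` | mM | 0.02 | I | Km-type constant |
| `k_glnk` | mM | 0.02 | II | regulatory half-saturation, indirectly known |
| `n_glnk` | – | 2 | US | Hill coefficient, fixed |
| `mu_max` | mM/min | 4 | I | growth-linked consumption, well characterized |
| `k_growth` | mM | 1 | III | invented lumped constant, penalty-free |
| `k_dil` | 1/min | 0.05 | US | dilution, fixed |

The defaults are simultaneously the ground truth of the shipped synthetic
scenarios (`default_scenario()`), so a single canonical parameterization
runs through the package.

### Numerical choices

The right-hand side is compiled C (`src/toy_model.c`, deSolve
compiled-code convention) because the GA needs $10^3$–$10^4$ steady-state
evaluations per fit; the plain-R `toy_rhs()` path is retained and
cross-checked against it in the tests. Integration uses `lsoda`
(`rtol = 1e-8`, `atol = 1e-10` for trajectories). Steady states
(`steady_state_toy()`) are found by chunked integration with doubling
horizon until the relative derivative norm falls below `tol = 1e-9`,
failing explicitly beyond `t_max = 2e5` min; integration was chosen over a
Newton solver to reuse the single compiled RHS and because candidate
parameter vectors far from the truth can be stiff. Step inputs (N-upshift)
are integrated piecewise between step times.

## The synthetic study generator

Real training data are replaced by a transparent generator
(`synthetic_scenario()`, `realize_scenario()`) so that the entire
pipeline is testable end to end:

* **References** emulate the uncertainty classes: reference = truth
  $\times\, e^{\sigma_c z}$, $z \sim N(0,1)$, with $\sigma_\mathrm{I} =
  0.1 < \sigma_\mathrm{II} = 0.4 < \sigma_\mathrm{III} = 1.0$; US
  references equal the truth exactly.
* **Observations** simulate the truth and apply multiplicative noise
  `value * (1 + cv * z)` (default cv = 0.03), bounded away from zero.
  Because cv $\le \varepsilon/3$ for every shipped constraint, the truth
  itself is always feasible (*self-consistency*, asserted in the tests).
* Everything is seeded; unseeded generation is refused, and equal seeds
  reproduce byte-identical artifacts.

What the generator does **not** emulate: correlated measurement errors,
systematic biases between labs, missing data, and model discrepancy (the
generating model is the fitted model). It tests the estimation machinery,
not robustness to misspecification.

The shipped `default_scenario()` trains on three conditions (N-upshift
time course 4 → 100 µM, a low-ammonium steady state at 4 µM, and a GlnK
knockout steady state at 100 µM; 8 constraint sets, 18 observations,
8 searched parameters). A finite-difference sensitivity rank test at the
truth confirms the design is identifiable (full rank 8).

## The two-model ranking experiment

`make_two_model_scenario()` generates one observation set from the
*active-transport* truth and hands the identical specs and constraints to
both the active and the passive variant; only the transport physics
differs. Observables are restricted to glutamine, growth rate and net
nitrogen uptake at 50 µM and 100 µM external ammonium — quantities both
mechanisms can in principle reproduce (internal NH$_4^+$ is excluded: the
passive variant is structurally capped at $0.25\times$ external NH$_4^+$
and could never fit it, which would decide the comparison by brute
feasibility rather than plausibility). Tolerances are $\varepsilon = 0.3$
(concentrations, fluxes) and $0.15$ (growth rate): wide enough that the
passive variant's feasible region, a small corner of its search box with
strongly distorted capacities, is reachable by the GA within a CI budget.

`two_model_experiment()` freezes the protocol: scenario seeds 1–5, GA
budgets 4000 (active) / 12000 (passive) evaluations. The active variant
fits with $f \approx 0.01$–$0.03$ while the passive variant must pay
$f \approx 2$–$9$ in class II penalties, so the plausibility ratio
favours the active mechanism in every seed (6.5× to ~10⁴×). The package
asserts only the direction, not a particular ratio.

## Problem sizes and runtimes (one CPU)

| task | size | time |
|---|---|---|
| one steady-state evaluation (compiled) | 3 states | ~2–4 ms |
| synthetic recovery (`default_scenario`, seed 42) | d = 8, 6000 evals | ~30 s |
| two-model ranking (`two_model_experiment`) | 5 seeds × 2 fits | ~4–5 min |
| full test suite | 568 assertions | ~6 min |

## Design decisions and open questions resolved

* **Objective vs. constraints**: the roles are fixed by the method — data
  may never be traded against the prior, only against feasibility.
* **Aggregator for replicate runs**: the representative $f$ per side in
  `compare_models()` is the **median** over feasible runs (robust to one
  bad run); `min` and `mean` are available.
* **Star crossover**: the exact rank-bias of REX\* is implemented as a
  rank-weighted centroid shift behind a flag (`star = TRUE`), with plain
  REX available, since several variants circulate in the literature.
* **Stall detection** uses a relative 0.1 % improvement margin so the
  iterative restart actually triggers on asymptotic plateaus.
* **Infeasible sentinel**: solver failures yield $\gamma = +\infty$ and
  rank last under every $p_f$.

## Limitations

* The demonstration network is a caricature: one lumped assimilation
  flux, no GS/GDH/GOGAT split, no explicit proton-motive-force dynamics,
  fixed pH and membrane potential.
* The plausibility weights $\lambda$ are taken as published constants;
  the package does not re-derive them from an error model.
* The GA is single-threaded; large problems (hundreds of parameters)
  would need parallel evaluation.
* Ranking compares exactly two variants; multi-model comparison is left
  to repeated pairwise calls.

## A minimal session

```{r example}
library(rubberband)

# 1. generate a synthetic study
real <- realize_scenario(default_scenario(seed = 42))

# 2. fit with the constrained GA
problem <- fitting_problem(real$specs, real$constraints, real$conditions)
run <- ga_optimize(problem, ga_config(length(problem$lower),
                                      max_evaluations = 6000, seed = 1))
print(run)

# 3. feasibility and plausibility of the best fit
evaluate_fit(run$best$values[problem$names], real$specs,
             real$constraints, real$conditions)

# 4. rank the active against the passive transport variant
res <- two_model_experiment(seeds = 1:5)
res[, c("seed", "f_active", "f_passive", "mp_ratio", "active_wins")]
```
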