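# crimedyn

Evolutionary game dynamics of organised crime, terrorist networks and
lone-wolf offending.

`crimedyn` is for researchers in quantitative criminology, evolutionary
game theory and statistical physics of social systems who want to study
how recruitment into illicit organisations responds to punishment. It
implements a three-role N-player adversarial game — honest citizens
(*H*), members of a criminal or terrorist organisation (*C*), and
unaffiliated lone wolves (*W*) — and follows its population dynamics
from exact group payoffs all the way to phase diagrams and agent-based
simulation.

## The model in brief

Groups of $N$ players are drawn from a well-mixed population of $Z$.
Each game has an **acting stage** — one member is drawn uniformly; a
criminal always offends, a wolf offends with probability
$p'_W = 1-\delta(1-p_C)$ (propaganda coupling), damaging victims by
$c_k$ and collecting $r_k c_k$ per victim, with criminals pooling loot
and receiving a fraction $\tau$ of wolf loot — and an **investigation
stage**, where the offender may be punished by the state ($\beta_S$),
civil society ($\beta_H p_H$) or, for wolves, the organisation itself
($\beta_C p_C$), with co-offender punishment reduced by $\gamma$.
Expected focal payoffs per composition are closed-form
(`acting_payoffs()`, `investigation_payoffs()`).

On top of these the package provides:

* **Mean field**: hypergeometric averaging over group draws
  (`mean_payoffs()`) and the replicator flow
  $\dot x_k = x_k(\omega_k-\bar\omega)$ on the simplex
  (`replicator_flow()`, `flow_field()`).
* **Finite-population Markov chain**: one-individual-per-step
  discretisation of the flow over all $(Z+1)(Z+2)/2$ states,
  $\mu$-regularised, with stationary distribution and regime labels
  (`build_transition_matrix()`, `stationary_distribution()`,
  `summarize_distribution()`).
* **Monte Carlo validator**: stochastic game realisations whose
  expectations equal the analytic payoffs, Fermi imitation with
  mutation, replicate-averaged trajectories (`run_simulation()`).
* **Analysis**: scenario presets (`scenario_preset("CO")`,
  `"TN-baseline"`, `"TN-propaganda"`, `"TN-transfer"`), analytic
  two-type invasion thresholds (`analytic_thresholds()`,
  `pairwise_sign_test()`), phase-diagram sweeps and threshold detection
  (`sweep_phase_diagram()`, `detect_threshold()`).
* **I/O and CLI**: CSV/JSON artifacts with embedded parameters
  (`run_command()`, `load_run_config()`) and a command-line wrapper in
  `inst/scripts/crimedyn`.

## Worked example

A strong state facing an organisation that punishes its lone-wolf
rivals hard:

```r
library(crimedyn)

p <- scenario_preset("CO", beta_S = 150, beta_C = 400, beta_H = 0)
dist <- stationary_distribution(build_transition_matrix(p))
summarize_distribution(dist)
#> regime: honest dominance
#>   E[x_H] = 0.9407, E[x_C] = 0.0086, E[x_W] = 0.0507
#>   most visited states:
#>   z_H z_C z_W        pi
#> 1  50   0   0 0.9152589
```

At $\beta_S = 150$ the population spends 92% of its time in the
all-honest configuration: the expected honest fraction is 0.94, and the
few percent of criminal and wolf presence is the re-seeding produced by
the $\mu = 10^{-6}$ mutation leak. That is what the analytic two-type
condition predicts — honests defeat wolves once
$\beta' = (\beta_S + \beta_H x_H)/c$ exceeds $N^2 = 100$:

```r
analytic_thresholds(model_params(N = 10, Z = 10, beta_S = 150),
                    group_composition(5, 0, 5))
#> $beta_prime       150
#> $beta_prime_HW    100
#> $honest_beats_wolf TRUE
```

Group-level payoffs are available directly; here a group of 8 honests,
1 criminal and 1 wolf at unit damages and rewards:

```r
acting_payoffs(group_composition(8, 1, 1), model_params())
#> focal payoffs: w_H = -0.2, w_C = 0.8, w_W = 0.8
#>   (b_C = 0.9, b_W = 0.9, d_C = 0.1, d_W = 0.1)
```

The honest citizen loses 0.1 to each type of offender in expectation;
criminal and wolf each net 0.8 before any punishment.

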