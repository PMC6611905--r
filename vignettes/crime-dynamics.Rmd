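---
title: "Modelling the evolutionary dynamics of organised crime and lone wolves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolutionary dynamics of organised crime and lone wolves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crimedyn)
```

## The model

`crimedyn` studies recruitment into criminal organisations (CO) and
terrorist networks (TN) as an evolutionary game. A well-mixed population
of $Z$ individuals holds three roles: *honest citizens* ($H$), who never
offend; *criminals* ($C$), affiliated to a single organisation that
shares loot and collective punishment; and *lone wolves* ($W$),
unaffiliated offenders who victimise everybody else. Games are played in
randomly drawn groups of $N$ and have two stages.

**Acting stage.** One group member is drawn uniformly (probability
$p_1 = 1/N$ each). A drawn honest does nothing. A drawn criminal always
acts; a drawn wolf acts with probability
$p'_W = 1 - \delta(1 - p_C)$, where $p_k = n_k/N$ are the within-group
role fractions and $\delta \in [0,1]$ couples wolf activity to criminal
presence (propaganda: with $\delta = 1$ wolves act only when the
organisation is represented in the group). An act damages each victim by
$c_k$ and yields the victimiser $r_k c_k$ per victim; criminals share
their loot equally within the group and do not harm each other, whereas
a wolf harms everyone and keeps a fraction $1 - \tau$ of her loot, the
remaining fraction $\tau$ being credited to the organisation (the
reputational gain of a network that claims the attack). In expectation,
with $b_C = r_C c_C (1 - p_C)$, $d_C = c_C p_C$,
$b_W = r_W c_W (N-1) p_1 p'_W$ and $d_{W|N'} = c_W p'_W N'/N$:

$$w^A_H = -d_C - d_{W|n_W}, \qquad
  w^A_C = b_C + \tau b_W - d_{W|n_W}, \qquad
  w^A_W = (1-\tau) b_W - d_C - d_{W|n_W - 1}.$$

The $\tau b_W$ credit in $w^A_C$ is taken literally: it does not scale
with the number of wolves in the group. As a consequence the acting
stage is exactly conservative
($n_H w^A_H + n_C w^A_C + n_W w^A_W = 0$) when $\tau = 0$ and
$r_C = r_W = 1$ — a property the test suite checks exhaustively for all
compositions up to $N = 12$ — but *not* when $\tau > 0$ and the group
holds two or more wolves. We deliberately did not "repair" this by
dividing the credit among wolves; fidelity to the printed stage payoffs
takes precedence, and the agent-based realisation (below) reproduces the
same expectation.

**Investigation stage.** A victimiser must first act and may then be
identified when a uniformly drawn group member is inspected. Punishment
intensity combines the state ($\beta_S$, always available), civil
society ($\beta_H$, effective in proportion to the honest share $p_H$),
and — against wolves only — the criminal organisation ($\beta_C$,
effective in proportion to $p_C$). A caught criminal also drags down her
group co-offenders, who receive the punishment scaled by
$\gamma \in [0,1]$:

$$w^I_H = 0, \qquad
  w^I_C = -(\beta_S + \beta_H p_H)\, p_C\, [\gamma p_C + (1-\gamma) p_1],
  \qquad
  w^I_W = -(\beta_S + \beta_H p_H + \beta_C p_C)\, p_1^2\, p'_W.$$

Criminals are therefore easier to catch (any criminal in the group
betrays the organisation) but only wolves can be punished by the
organisation itself.

## Mean field, replicator flow and the finite-population chain

Group compositions are drawn without replacement from the population,
so the payoff of a focal individual of role $k$ in state
$\langle Z_H, Z_C, Z_W\rangle$ averages the stage payoffs over all
$(N-1)$-subgroups with multivariate hypergeometric weights
(`mean_payoffs()`, `subgroup_weight()`). The replicator flow
$\dot{x}_k = x_k(\omega_k - \bar\omega)$ (`replicator_flow()`,
`flow_field()`) lives on the 2-simplex of role fractions; vertices are
fixed points and extinct roles never re-enter.

Finite populations are analysed through a Markov chain over all
$(Z+1)(Z+2)/2$ states in which one individual changes role per step
(`build_transition_matrix()`). The discretisation is genuinely open —
"follow the flow to the closest next configuration" does not pin down a
unique rule — and we made these choices:

* the flow at the state is scaled so its largest component moves exactly
  one lattice unit $1/Z$, and the successor is the candidate state
  (itself or any one-individual move) closest in Euclidean distance to
  the displaced point; exact ties split the weight equally and a
  numerically zero flow ($\max_k |\dot{x}_k| \le 10^{-12}$) yields a
  self-loop. The rule is isolated in `successor_state()` so alternatives
  can be swapped in and compared.
* regularisation adds $\mu$ ($10^{-6}$ by default) to *every* matrix
  entry before renormalising, guaranteeing ergodicity
  (`mu_mode = "all"`). A neighbour-restricted reading, which adds $\mu$
  only to one-individual transitions, is available as
  `mu_mode = "neighbour"` for sensitivity analysis. The two differ in a
  subtle and instructive way: the all-entries leak re-seeds boundary
  edges where a role is extinct, so regions whose edge dynamics
  terminate elsewhere (e.g. the wolf-free honest–criminal edge) retain
  a few percent of occupancy that the neighbour mode does not show.
* states are enumerated lexicographically in $(z_C, z_W)$; any fixed
  order works, one must be declared for reproducible matrices.
* the stationary distribution solves $\pi P = \pi$ by a dense linear
  system with one equation replaced by normalisation, plus iterative
  refinement and a leading-eigenvector fallback for nearly reducible
  chains; the accepted residual is
  $\lVert \pi P - \pi \rVert_\infty \le 10^{-10}$.

`summarize_distribution()` reduces $\pi$ to expected fractions
$E[x_k]$, the most-visited states above 10% of the maximum probability,
and a regime label. The labelling thresholds (dominance at
$E[x_k] \ge 0.8$, eradication at $E[x_C] + E[x_W] \le 0.05$) are
reporting conventions, not model quantities.

## The Monte Carlo validator

`run_simulation()` realises the game stochastically: each iteration
shuffles the population into $Z/N$ groups $G$ times, draws one actor per
group, realises acting and investigation as random events whose
expectations equal the stage payoffs exactly (the punishment magnitudes
$\beta_H p_H$, $\beta_C p_C$ are applied as deterministic
group-dependent quantities; only the identification events are random —
the minimal randomness consistent with the printed expectations), and
then applies one asynchronous update: with probability $\mu$ a uniformly
chosen agent mutates to a uniform role, otherwise a random agent imitates
another with the Fermi probability
$P(i \leftarrow j) = 1/(e^{-(\omega_j - \omega_i)/T} + 1)$ computed from
the $G$-game average payoffs. The temperature $T$ is not fixed by the
reference parameterisations; the default $T = 1$ (payoff units) puts
typical single-game payoff differences (order 1) in the responsive part
of the sigmoid, and simulation-based checks compare regimes, not time
constants. Wolf-loot transfer pays each group criminal
$\tau r_W c_W (N-1)/n_W$ per wolf act, which reproduces the literal
$\tau b_W$ credit of the mean field, including its non-conservation.

The model itself is the data generator: there is no external data, and
the reference study conditions are the preset parameterisations
($\gamma = 0.5$, $N = 10$, $Z = 50$, $c_C = c_W = r_C = r_W = 1$,
$\mu = 10^{-6}$; `scenario_preset()`). What the simulator emulates is a
well-mixed society with complete, noisy payoff information; it does not
emulate network structure, heterogeneous damages, retaliation, or
multiple competing organisations, so agreement between simulator and
mean field validates the sampling and update rules, not those richer
features of real criminal ecosystems.

## Analytic thresholds and a recorded discrepancy

In the single-group limit $N = Z$ with $\delta = \tau = 0$,
$c_C = c_W = c$, $r = 1$, pairwise competition reduces to closed forms
in $\beta' = (\beta_S + \beta_H p_H)/c$ and
$g = (1-\gamma)p_1 + \gamma p_C$ (`analytic_thresholds()`): honests
defeat wolves iff $\beta' > N^2$, and defeat criminals iff
$\beta' > (g\,p_C)^{-1}$. For the criminal–wolf competition the direct
payoff difference is
$\omega_C - \omega_W = (\beta_S + \beta_C p_C)/N^2 - \beta_S\, g\, p_C$,
giving the boundary $\beta_C = (N^2 g p_C - 1)\beta_S / p_C$. The
compact form $(N^2 g p_C - 1)\beta_S$ sometimes quoted for this
boundary differs by the factor $1/p_C$ (e.g. $28\,\beta_S$ versus
$14\,\beta_S$ at $n_C = n_W = N/2$, $\gamma = 0.5$, $N = 10$);
`pairwise_sign_test()` brute-forces the sign change and the test suite
records that it follows the payoff-derived form. Both values are
reported side by side rather than silently "fixing" either.

## Numerical choices and problem sizes

Binomial coefficients are computed through `lchoose()` sums, exact to
well below the $10^{-12}$ payoff tolerance at $Z = 50$ scale; no
tolerance is applied inside payoff formulas themselves. Probability
sums are checked at $10^{-9}$. Test problem sizes were chosen so each
layer is checked by an independent oracle at a scale where the oracle
is exact: payoff conservation exhaustively to $N = 12$; mean-field
versus explicit enumeration of all $\binom{Z-1}{N-1}$ draws at
$Z = 12$, $N = 4$; Monte Carlo versus mean field over $10^5$ games at
the reference $Z = 50$, $N = 10$; simulator drift over 400 iterations
and 6 replicates at $G = 10$. Phase-boundary scans build one
$1326$-state chain per grid point; the reference scans use the grids
$\beta_S \in \{0, 25, \dots\}$, $\beta_C \in \{0, 10, \dots\}$,
$\beta_H \in \{0, 250, \dots\}$, which resolve the analytic boundaries
at a second or two per cell.

## Known limitations

* The stationary phase diagram inherits the ambiguity of the one-step
  discretisation. Where the analytic two-type conditions apply, the
  chain reproduces them (the honest take-over of wolves at
  $\beta' \approx N^2$ is recovered to grid resolution); in cycling
  regions of the simplex, different faithful discretisations and
  $\mu$ readings redistribute occupancy substantially, and the package
  exposes both $\mu$ modes so users can gauge that sensitivity.
* With civil punishment only ($\beta_S = 0$), the wolf corner of the
  simplex is locally attracting for every $\beta_H$ (punishment scales
  with the honest share, which vanishes there), so expected honest
  fractions saturate below full eradication under the all-entries
  $\mu$ leak.
* The ODE-in-time view of the replicator dynamics is intentionally not
  integrated; the finite chain is the object of study, and `flow_field()`
  provides the numeric vector field for anyone who wants trajectories.
* The agent simulator is asynchronous (one imitation or mutation per
  iteration); generational updating, structured populations and
  retaliation are out of scope.
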