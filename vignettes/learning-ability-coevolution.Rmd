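---
title: "Winner-weaken-loser-strengthen: coevolving learning ability in the spatial prisoner's dilemma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-weaken-loser-strengthen: coevolving learning ability in the spatial prisoner's dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcoev)
```

## The model

`pdcoev` simulates the weak prisoner's dilemma on an L x L square lattice
with periodic boundary conditions and von Neumann (4-site) neighbourhoods.
Each player holds a strategy, cooperate (C) or defect (D), and a *learning
ability* w in [0.1, 1].  Payoffs are fully parameterized by the temptation
b: a defector earns T = b against a cooperator, mutual cooperation pays
R = 1, and S = P = 0, with 1 < b <= 2 so that T > R > P >= S.  A player's
payoff in a configuration is the sum of its pairwise payoffs against its
four neighbours.

Dynamics are asynchronous Monte Carlo: an elementary step draws a random
focal player x and a random neighbour y and lets x copy y's strategy with
the Fermi probability

$$W = w_x \, \frac{1}{1 + \exp[(P_x - P_y)/K]},$$

where K = 0.1 is the adoption noise and the prefactor w_x scales the
whole probability — a conservative player (low w) rarely imitates even a
much richer neighbour.  After the adoption attempt the focal player's
learning ability is updated by the *winner-weaken-loser-strengthen* rule:
with $\bar P_x$ the mean payoff of x's neighbours,

$$w_x \leftarrow \begin{cases} w_x + d, & P_x < \bar P_x,\\
                               w_x - d, & P_x \ge \bar P_x,\end{cases}$$

clamped to [0.1, 1].  Winners (including ties, e.g. the interior of a
uniform domain where every payoff equals the environment average) become
more conservative; losers become more eager to change.  The increment d
in [0, 1] controls how fast heterogeneity builds up; d = 0 recovers the
classical homogeneous game.  Three gating rules restrict who evolves w:
rule I (everyone), rule II (cooperators only), rule III (defectors only).

One full MC step performs L^2 elementary updates (selection with
replacement), so each player updates once on average.  Simulations start
either from a uniform random 50/50 strategy assignment with every w = 1,
or from the four-bar block configuration (`four_bar_initial()`) used to
watch boundary dynamics between blocks with extreme learning abilities.

## What the package computes

The headline observable is the stationary cooperation density f_C and,
derived from it, the extinction threshold b_C: the smallest temptation at
which cooperation vanishes.  `run_to_stationarity()` advances a world and
averages f_C over a trailing window; `estimate_extinction_threshold()`
scans a b grid with independently seeded replicates and brackets b_C
between the largest surviving and smallest extinct grid point (midpoint
reported).  `decompose_end_exp()` splits a trajectory at the minimum of
its smoothed f_C into the enduring period (cooperators are invaded and
retreat into compact clusters) and the expanding period (clusters grow
back through network reciprocity).  `learning_ability_stats()` summarises
w by strategy class, separately for boundary players — the mechanism
behind the three rules' different outcomes is precisely the w contrast
across C/D interfaces.

The qualitative picture this machinery reproduces: under rule I and rule
III increasing d suppresses cooperation (b_C falls towards 1), whereas
under rule II cooperation is promoted, with the threshold gain largest at
the intermediate d = 0.05 — boundary cooperators become conservative
holders of their strategy while defectors, whose w never falls, keep
imitating the cooperators exploiting the cluster structure.

## Numerical and design choices

* **Update scheme.** Asynchronous random sequential updating with
  replacement, L^2 elementary draws per MC step.  Synchronous updating is
  deliberately not implemented.
* **Payoff evaluation.** All payoffs entering one elementary step
  (focal, chosen neighbour, environment average) are evaluated on the
  pre-adoption configuration; the w update reuses them.  "w evolves after
  strategy adoption" is thus an ordering of operations within the step,
  not a re-evaluation of payoffs.
* **Rule gating basis.** Whether a focal player counts as cooperator or
  defector for rules II/III is judged on its post-adoption strategy by
  default (`gating_basis = "post_adoption"`); the pre-adoption variant is
  available as an option.  With rule I the choice is immaterial.
* **w is a persistent attribute.** A player that switches strategy keeps
  its w; rules II/III only freeze its *evolution* while the player holds
  the non-evolving strategy.
* **Ties.** P_x = P̄_x takes the decrease branch (the interior of uniform
  domains drains to w_min, which is why w_min = 0.1 exists at all — it
  prevents frozen, unreactive domains).
* **Bounds.** w_max = 1.0: increments are clamped so the Fermi prefactor
  stays a valid probability weight.  The minimum 0.1 keeps every player
  minimally responsive.
* **Overflow.** The Fermi exponent is clipped at ±700, saturating the
  probability smoothly to 0 or w_x.
* **Restricted comparison sets.** `comparison_set = "same_strategy"` /
  `"different_strategy"` average the environment payoff over only the
  matching neighbours; an empty set leaves w unchanged for that step and
  is counted in the run's `empty_comparison` tally.
* **Extinction criterion.** A grid point counts as extinct when the
  stationary f_C is below eps = 1e-3 in *all* replicates (at L = 100,
  fewer than a handful of cooperators).  Early stopping on absorption is
  on by default in scans, since all-C/all-D states are strictly
  absorbing for the strategy dynamics.  A surviving point isolated above
  an extinct one is re-resolved by majority over its replicates.  When
  every tested b is extinct, the bracket is closed against the
  weak-dilemma limit b = 1 and the midpoint reported against it.
* **Seeding.** Every stochastic entry point takes a seed; replicate sets
  derive per-replicate child seeds deterministically from one top-level
  seed, so scans are reproducible independent of execution order.
  An elementary update consumes exactly three uniform draws (site,
  neighbour, acceptance), making whole trajectories bit-reproducible.

## Problem sizes

Full-scale studies of this model use L = 100–400, 5e4–1e5 MC steps with
the stationary density averaged over the last 5e3 steps, and 20
realizations per point.  The package defaults are desk-scale choices
that preserve the phenomenology while keeping a complete analysis in the
minutes range: L = 100, 2e4 steps, a 2e3-step trailing window
(`schedule()`), and 5–10 replicates; threshold-ordering comparisons
(e.g. the rule II optimum) use L = 60 with 6e3 steps and a grid spacing
of 0.0025 around the contested region, and fixed-b density comparisons
use L = 70–100 with 6e3–8e3 steps (relaxation at these temptations is
complete within ~2e3 steps).  The paper-scale settings remain one
`schedule(5e4, 5e3)` away.

## What the synthetic initial conditions do and do not emulate

The two built-in initializers cover the standard preparations of this
literature: unbiased random mixtures (for density curves and thresholds)
and block interfaces with extreme w (for mechanism snapshots).  They do
not emulate empirical interaction networks, degree heterogeneity, or
noise in the initial learning abilities; the generalized-graph contract
(`world_from_graph()`) accepts arbitrary symmetric graphs, but all
quantitative statements in the tests are about the periodic lattice.
Passing tests therefore demonstrate the lattice phenomenology, not
claims about real social systems.

## Known limitations

* At desk scale the rule I threshold at d = 0.08 sits slightly above 1:
  with L = 100 and 2e4 steps, cooperation still coexists at
  b <= 1.01 (stationary f_C ≈ 0.37 at b = 1.005 even after 5e4 steps),
  so the estimated b_C lands near 1.015 rather than collapsing fully to
  1.  The suppression trend in d and the threshold ordering across rules
  are robust; the absolute collapse point at this d is the one
  quantitative statement that remains size- and schedule-sensitive.
  The engine itself reproduces the classical homogeneous benchmark
  (b_C between 1.035 and 1.04 at d = 0, K = 0.1) accurately.
* The restricted comparison-set variants are implemented by their
  literal description (selection against the focal player's pre-adoption
  strategy) and carry no quantitative targets.
* Replicates run serially; the deterministic child-seed scheme makes a
  parallel driver a drop-in extension.

## A short session

```{r example, eval = FALSE}
library(pdcoev)

p <- game_params(b = 1.02, d = 0.05, rule = "II")
run <- run_to_stationarity(random_initial(100, seed = 1), p,
                           schedule(10000, 2000), seed = 1)
run$stationary_f_C          # ~0.49: rule II sustains cooperation

dec <- decompose_end_exp(run)
dec$t_min                   # end of the enduring period

sc <- estimate_extinction_threshold(
  game_params(b = 1.05, d = 0.05, rule = "II"),
  b_grid = seq(1.0325, 1.0525, by = 0.0025),
  reps = 5, seed = 21, L = 60, schedule = schedule(6000, 1500))
sc$b_C                      # threshold estimate with its bracket
```
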