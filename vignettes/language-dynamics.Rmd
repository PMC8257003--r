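---
title: "Bayesian agents on communicative networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian agents on communicative networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingnet)
```

## The question and the model

Speech communities are not homogeneous: some speakers carry intrinsic
preferences — articulatory, cognitive, or social — for one variant of a
linguistic feature. `lingnet` simulates whether and how such a biased
minority shapes the language that a structured community converges on.

The language is reduced to a single obligatory binary feature. An agent's
knowledge of the language is a belief about `h`, the probability that the
community produces variant "1". Beliefs are Beta distributions, so
learning is conjugate: after hearing `k` ones among `n` utterances, a
`Beta(α, β)` belief becomes `Beta(α + k, β + n − k)`. An agent's *language
value* is the mode of its current Beta belief — its best single guess of
`h`.

Utterance production is a two-stage race: the agent first commits to a
value of `h` — samplers (SAM) draw it from the full posterior, maximizers
(MAP) take the posterior mode — and then flips a `Bernoulli(h)` coin.
Because pseudo-counts only accumulate, beliefs get harder to move as a
run progresses: early utterances matter more than late ones, and the
SAM/MAP distinction fades as posteriors sharpen. Note that concentration
is not pointwise monotone — a single surprising utterance (a "1" heard by
a strongly "0"-skewed agent) momentarily *widens* the posterior — but the
variance envelope `1/(4(α + β + 1))` shrinks with every utterance heard,
and the tests pin down both facts.

## The bias scale

A bias is the pair `(μ₀, λ₀)`: the preferred value of `h` and how
strongly it is held. The package maps this to prior shape parameters as

```
ν  = 70 (1 − λ₀)²
α₀ = 1 + μ₀ ν,   β₀ = 1 + (1 − μ₀) ν
```

which guarantees `α₀, β₀ ≥ 1` (so the mode formula is always valid),
places the prior mode exactly at `μ₀` for every strength, and makes the
density flatten monotonically as `λ₀ → 1`. `λ₀ = 0` is special: a *fixed*
agent, a point mass at `μ₀` that ignores all data and produces
`Bernoulli(μ₀)` forever — the limit of an infinitely concentrated prior,
implemented as its own role rather than through the formula.

The two constants of the concentration law are the one genuinely free
design choice in the model, because "bias strength" has no canonical
unit. We anchored them empirically: replicated 150-agent sweeps (the
`figure8` preset; 50 replications, 500 iterations, initial language of
four "1" utterances) must reproduce the two reference aggregated language
values for this model family — 0.67 at strength 0.70 with 35% biased
agents, and 0.22 at strength 0.15 with 80% biased agents. A
self-consistent scan over `ν = a(1 − λ₀)^γ` gave `a = 70, γ = 2`; the
package's acceptance script recomputes both aggregates (we observe
0.66–0.67 and 0.22–0.23 across base seeds). Simpler one-parameter laws
(for example `ν = (1 − λ₀)/λ₀`) miss both anchors by 0.15–0.30 in
language value. The whole mapping lives in one internal function
(`prior_concentration`) so an alternative scale can be swapped in without
touching anything else. Under the calibrated scale the unbiased reference
profile `(0.5, 0.9)` is the gently domed `Beta(1.35, 1.35)` — flat enough
that four initial utterances dominate it.

## Networks

Agents occupy a static, undirected, unweighted graph; neighbors are the
only listeners. Three generator classes are provided, with the study
defaults:

| class | generator | defaults | mean degree |
|---|---|---|---|
| random | Erdős–Rényi `G(N, p)` (igraph) | `density = 0.1` | `0.1 (N−1)` |
| small-world | Watts–Strogatz beta model | 4 neighbors per side, `rewire_p = 0.1` | 8 |
| scale-free | Barabási–Albert preferential attachment | `m_attach = 4`, clique seed of 5 | ≈ 8 |

The Watts–Strogatz rewiring replaces only the far endpoint of a lattice
edge and skips self-loops and duplicates, so the edge count is exactly
`4N` at any rewiring probability. The Barabási–Albert generator grows
from a fully connected seed of `m + 1` nodes, attaching each newcomer to
`m` distinct nodes sampled proportional to degree, giving exactly
`C(m+1, 2) + m(N − m − 1)` edges. `m_attach = 4` makes the scale-free
mean degree match the small-world lattice, so cross-topology comparisons
are degree-matched. "Influencers" are the highest-degree nodes, ranked
deterministically (ties broken by id); degree is the conventional
centrality for hub-based seeding and is isolated behind
`rank_centrality()` for substitution.

Disconnected graphs are accepted as-is: isolated agents simply never
interact. This matters at small sizes — `G(50, 0.1)` is disconnected in
roughly half of the seeds, and independently drifting components then
dominate the between-community heterogeneity statistic. This is a genuine
property of sparse random graphs, not an artifact, but it is why the
structured-versus-random heterogeneity contrast is evaluated at
`N = 150`, where the random graphs are connected.

## The interaction protocol

Time is discrete. Iteration 0 is the initial condition: every non-fixed
agent may first be exposed to a shared batch of `k₀` ones out of `n₀`
utterances (`init_k0 = init_n0 = 4` models a pre-existing convention
favoring "1"; `0/0` models a community with no prior language). Each
subsequent iteration draws a fresh uniform permutation of the agents;
each agent speaks exactly once, and the utterance is heard by all its
neighbors. In the default *asynchronous* mode every listener updates
immediately, so agents later in the permutation speak from
already-updated beliefs; in *synchronous* mode heard counts are
accumulated and applied once at the end of the iteration. The two modes
give very similar outcomes (the suite checks that replication-averaged
final values differ by under 0.05 on the flagship condition); the
asynchronous mode is the default because a listener in conversation does
not wait for a census tick.

Speakers never hear themselves (the generators emit no self-loops), and
production never alters the producer's own state. One consequence used as
a hard invariant: in an asynchronous run every non-fixed agent's
pseudo-count total obeys `αᵢ + βᵢ = α₀ + β₀ + n₀ + t·deg(i)` exactly at
every iteration `t`.

The inner loop is compiled (Rcpp) and draws all randomness from R's RNG,
so a run is byte-for-byte determined by its master seed. From that seed
the package derives independent child seeds — for network generation,
role assignment, the interaction loop, and Louvain community detection —
by hashing the seed with a component label (`derive_seed()`), so changing
one stochastic component leaves the others' streams intact. Grid cells
hash `(base seed, condition key, replication index)`, which makes any
single cell re-runnable in isolation.

## Outcome statistics

- **Group language value**: the arithmetic mean of member language
  values; recorded every iteration for the whole population and the
  biased/unbiased groups. An empty group yields `NA`, never 0.
- **diff**: `mean(unbiased) − mean(biased)` — identical, by linearity, to
  the mean of all pairwise differences at a fraction of the cost.
- **Heterogeneity**: Louvain communities are detected once, from the
  connection structure only, and the statistic is the sample standard
  deviation (denominator `m − 1`) of per-community mean language values.
  A single community reports 0 (zero dispersion is the truthful value);
  networks of at most 10 agents report `NA`, as communities of 2–3 agents
  are not meaningful.
- **Stabilization time**: with window `ω = I/10`, each window start `g`
  gets the scaled slope `(e(g+ω) − e(g))/ω × 10 000`, rounded half away
  from zero; the reported tick is the first `g` whose rounded slope is
  zero and stays zero for the 50 following windows. Rounding half away
  from zero makes the practical zero criterion `|slope| < 5×10⁻⁵` per
  iteration, and the detector's behavior flips exactly at that boundary
  (tested against a literal window-by-window enumeration). A series that
  never qualifies reports the sentinel `I` with `stabilized = FALSE`
  rather than a missing value, keeping result tables rectangular. The
  detector always consumes the per-iteration series; the `record_every`
  stride thins only CSV exports.
- **Inter-replication sd**: the sample standard deviation of final
  whole-population values across a condition's replications.

## Sweeps, presets, and statistical helpers

`run_grid()` runs the cartesian product of condition values times
replications, appends rows to CSV as they complete, and records per-cell
failures without aborting. Three presets ship with the package: the
`figure8` systematic design (150 SAM agents, initial language, random
placement, 500 iterations, 50 replications, sweeping bias strength and
frequency), and two scaled-down smoke designs (`main-smoke`,
`systematic-smoke`) that echo the full study's contrasts at desk scale.
`isolines()` reports, for each requested language-value level, the
frontier cell of the sub-level set in every bias-strength column — the
smallest biased fraction that already pulls the population to that level;
on a monotone surface this is the level-set boundary, and frontier cells
bracket the level against their upsilon-predecessor.
`ranksum_bonferroni()` uses the exact rank-sum null when both sides have
at most ten untied values and the continuity-corrected normal
approximation otherwise, then multiplies by the family size (capped at 1).

## What the simulations do and do not show

The default conditions are the study conditions: 150 agents (10–1000 in
the smoke designs), unbiased profile `(0.5, 0.9)`, biased profiles at
`μ₀ = 0.1`, initial language `4/4`, 500–1000 iterations, 10–50
replications. The test suite runs everything at these desk scales; the
qualitative checks (a biased minority dragging the unbiased majority;
more dialect differentiation on scale-free than on random networks at
`N = 150`; language value monotone in bias strength and frequency on a
5×5 grid with 30 common-random-number replications per cell) are echoes
of the full-grid findings, not reproductions of full-grid statistics —
the full design (720 conditions × 100 replications × 5000 iterations, up
to 1000 agents) is out of scope by construction. Common random numbers
are used in the monotonicity check so that cells sharing a replication
index share networks and production draws; without them, rows in which a
parameter has no effect (for example, bias strength when nobody is
biased) would differ only by Monte-Carlo noise.

The model abstracts aggressively: one binary feature (no multi-feature
languages or continuous variants), a single production strategy per run,
static unweighted undirected networks (no birth/death, no tie strength,
no directed influence), and no population turnover or contact between
communities. Passing tests therefore say nothing about real acquisition
data; they certify the mechanics of the model and the reproducibility of
its statistics.

## Numerical and degenerate-case conventions

- Mode of `Beta(1, 1)`: defined as 0.5 (symmetric limit), so near-flat
  unbiased priors report 0.5 before any data.
- `update_posterior()` rejects `k > n` and negative counts; priors plus
  count updates keep `α, β ≥ 1` always, so the mode formula never leaves
  `[0, 1]`.
- Stabilization requires at least `ω + 51` windows and an iteration count
  divisible by 10; shorter series are an error, not a silent `NA`.
- Sample (`m − 1`) standard deviations everywhere, matching the default
  of the usual analysis environments.
- Seeds derived by `derive_seed()` stay below 2³¹.

```{r example}
run <- run_simulation(sim_config(size_net = 50, prop_biased = 0.1,
                                 lambda0 = 0.1, n_iterations = 200,
                                 seed = 1))
summary(run)
```
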