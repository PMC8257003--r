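# lingnet

Agent-based simulation of language change in structured populations.
`lingnet` asks a question from historical linguistics — can a minority of
speakers with an intrinsic preference for one variant of a linguistic
feature bend the language of a whole community? — and answers it with
Bayesian agents communicating over social networks. It is aimed at
researchers in cultural evolution, language dynamics and opinion dynamics
who need a fast, fully reproducible simulator with the standard outcome
statistics built in.

## The model

A community of `N` agents shares one binary linguistic feature (say,
trilled /r/ = "1" vs. any other rhotic = "0"). Each agent believes the
community produces "1" with some probability `h ∈ [0, 1]` and maintains a
Beta distribution over `h`:

- **Prior.** An agent's intrinsic bias is a pair `(μ₀, λ₀)`: `μ₀` is the
  mode of its prior Beta and `λ₀ ∈ [0, 1]` the bias strength. The prior is
  `Beta(1 + μ₀ν, 1 + (1 − μ₀)ν)` with concentration `ν = 70(1 − λ₀)²`,
  so `λ₀` near 1 is a weakly held, near-flat preference and small `λ₀` a
  strongly peaked one; `λ₀ = 0` is an immovable agent that no data can
  move. Unbiased agents carry the near-flat prior `(μ₀ = 0.5, λ₀ = 0.9)`.
- **Learning.** Hearing `k` ones out of `n` utterances updates the belief
  conjugately: `α ← α + k`, `β ← β + (n − k)`.
- **Speaking.** A *sampler* (SAM) draws `h ~ Beta(α, β)` afresh for every
  utterance; a *maximum-a-posteriori* (MAP) agent always uses the
  posterior mode `(α − 1)/(α + β − 2)`. Either way the utterance is a coin
  throw `Bernoulli(h)`.
- **Interaction.** Agents sit on a static undirected network (Erdős–Rényi,
  Watts–Strogatz small-world, or Barabási–Albert scale-free). Each
  iteration visits all agents in a fresh random order; each speaks once
  and all its neighbors hear (and, in asynchronous mode, immediately
  learn from) the utterance. Iteration 0 optionally exposes everyone to a
  shared "initial language" of `k₀` ones out of `n₀` utterances.

The outcome statistics are the *language value* (the mode of an agent's
Beta belief, averaged over groups), the signed unbiased-minus-biased
difference, *heterogeneity* (the standard deviation of mean language
values across Louvain communities — emergent dialects), and the
*stabilization time* (first iteration whose windowed slope, scaled by
10,000 and rounded, stays zero for 50 consecutive windows).

## A worked example

Ten percent of 150 sampler agents on a scale-free network hold a strong
intrinsic bias towards "0" (`μ₀ = 0.1, λ₀ = 0.1`); everyone first hears a
community convention of four "1" utterances:

```r
library(lingnet)
cfg <- sim_config(size_net = 150, network = "scale-free", learners = "SAM",
                  mu0 = 0.1, lambda0 = 0.1, prop_biased = 0.10,
                  init_k0 = 4, init_n0 = 4, n_iterations = 500, seed = 42)
run <- run_simulation(cfg)
summary(run)
#> Outcome statistics
#>   langval_all      0.76042
#>   langval_biased   0.73285
#>   langval_control  0.76348
#>   diff             0.03063
#>   heterogeneity    0.01181
#>   stab_biased      500 (not stabilized)
#>   stab_control     135
```

Reading this: the community convention strongly favored "1" (unbiased
agents start near 0.99 after exposure), yet a 10% biased minority has
dragged the whole population down to 0.76 — the minority is not swamped.
The biased agents themselves moved far from their preferred 0.1 but keep
a trace of the bias (`diff` > 0: they still use "0" more than their
unbiased neighbors). The eight Louvain communities differ only mildly in
their mean language (heterogeneity 0.012); the unbiased group's language
had stopped changing by iteration 135, while the biased group was still
drifting at the end of the run.

`plot(run)` draws the three group trajectories. Replicated parameter
sweeps run through `grid_spec()` / `grid_preset()` / `run_grid()` and
aggregate with `summarize_conditions()`; `isolines()` extracts
equal-language-value frontiers over the bias-strength × bias-frequency
plane, and `ranksum_bonferroni()` does the standard corrected rank-sum
comparisons. A thin command-line interface is installed at
`system.file("cli", "lingnet", package = "lingnet")` with `simulate` and
`grid` subcommands.

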