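---
title: "Passive, active and mixed contagion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive, active and mixed contagion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcontagion)
```

## The problem

When an idea, innovation or piece of content spreads over a social network,
two forces act on every individual: *peer pressure* (how many of my contacts
have already adopted?) and *personal preference* (do I actually like this?).
Classic epidemic-style models capture only the first force; purely
preference-driven models only the second. `netcontagion` simulates both
extremes and a mixed scheme on the same synchronous engine, so their
predictions can be compared on identical substrates, seed sets and random
streams.

Nodes are always in exactly one of three states: **susceptible**, **infected**
(an absorbing "has adopted" state — there is no recovery), or **blocked**
(an absorbing "will never adopt" state modelling refusal extremists or
randomly immunized individuals).

## The three models

Let $G=(V,E)$ be an undirected simple graph, and for node $n$ let $f_n(t)$ be
the fraction of its neighbors infected at the end of iteration $t$.

**Threshold (passive).** Node $n$ carries a threshold $\tau_n \in [0,1]$.
At iteration $t$, every susceptible node with $f_n(t-1) > \tau_n$ becomes
infected. The comparison is *strict*: with $\tau = 0$ a single infected
neighbor suffices, and a degree-13 node with $\tau = 0.2$ needs three
infected neighbors ($2/13 \le 0.2 < 3/13$); `min_infected_neighbors()`
computes this count. Given the seed set the model is fully deterministic.

**Profile (active).** Node $n$ carries a profile $\gamma_n \in [0,1]$
describing its reluctance toward the spreading content. Every susceptible
node with at least one infected neighbor runs *one* preference trial per
iteration: a uniform draw $v$ adopts iff $v \ge \gamma_n$, so the per-trial
adoption probability is $1-\gamma_n$ (20% at $\gamma = 0.8$). A refusing
node becomes permanently blocked with probability $p$ (the blocking
probability), otherwise it stays susceptible and may try again.

**Profile-threshold (mixed).** The preference trial is gated behind peer
pressure: only susceptible nodes with $f_n(t-1) > \tau_n$ run the trial, and
only those refusers risk blocking. Nodes below the gate are untouched.

**Spontaneous adoption.** Independently of the model, each iteration begins
with an exogenous pre-step: every susceptible node becomes infected with
probability $a$ (media, advertising). Blocked nodes never adopt, also not
spontaneously — blocking models categorical refusal.

Useful reductions, which the test suite exploits as oracles: profile-threshold
with $\gamma = 0$ is pathwise identical to the threshold model;
profile-threshold with $\tau = 0$ equals the profile model in distribution;
threshold with $\tau = 0$ spreads exactly as breadth-first-search layers; and
on an edgeless graph with spontaneous rate $a$ the expected susceptible
fraction decays as $(1-s_0)(1-a)^t$.

## Update discipline and reproducibility

Updates are synchronous: all decisions of iteration $t$ read the status
ledger as it stood at the end of iteration $t-1$ (spontaneous adopters of the
current iteration count as infected for the model step that follows them).
Random draws are made in vectorized passes over candidate nodes in ascending
node-id order — first the preference trials, then the blocking draws for the
refusers — so a run is a pure function of `(graph, params, seeds, rng_seed)`.
Every higher-level routine (protocol, grid sweep) derives per-run seeds from
one root seed via `derive_seed()`, which makes whole sweeps bit-reproducible
and lets an interrupted grid resume without changing any remaining row.

The iteration counter advances on model steps only. `Trend` entry $t$ is the
infected fraction after iteration $t$, entry 0 the seed fraction; it is
non-decreasing because both non-susceptible states are absorbing.

## Substrate networks

Three generators mirror a real online social network of 63392 nodes with
average degree 13:

* `generate_ba(n, m)` — Barabási–Albert preferential attachment, `m = 13`
  edges per new node. The initial-core convention is igraph's `sample_pa`
  (growth from a single vertex); the convention is recorded in the graph's
  `generator` attribute since different libraries seed the core differently.
* `generate_er(n, p)` — Erdős–Rényi with `p = 0.0004`. At `n = 63392` this
  edge probability implies a mean degree near 25 rather than 13; the value is
  kept as given (it is the documented study condition) and the discrepancy is
  visible in `graph_stats()` output.
* `generate_ws(n, k, p)` — Watts–Strogatz: a ring lattice joining each node
  to its `floor(k/2)` nearest neighbors per side, then each lattice edge
  rewired with probability `p` by replacing its far endpoint with a uniform
  random node (self-loops and duplicates redrawn, clashing redraws batched).
  With the study's `k = 13` the effective lattice degree is 12 — an odd
  uniform ring degree is impossible — which is the convention the common
  Python generators use as well. We implement the rewiring directly rather
  than through `igraph::sample_smallworld()`, whose rewiring semantics
  differ and measurably accelerate diffusion at these parameter values.

Arbitrary substrates come in through `load_edge_list()` (SNAP-style plain
text, labels mapped to dense internal ids, self-loops/duplicates dropped and
counted).

## Experimental protocol

`run_protocol()` reproduces the analytical protocol: sample `n_seed_sets`
random seed sets, each covering `seed_fraction` of $V$ (size rounded half-up;
defaults 100 sets of 5%), run the model for a fixed number of iterations
(default 30) from each, and aggregate by the iteration-wise mean trend and
the mean/sd of the final infected percentage. `run_grid()` repeats this for
every *valid* parameter combination — parameters a model ignores are not
swept for it, so the threshold model spans $\tau \times a$, the profile model
$\gamma \times p \times a$, and the mixed model all four — with default grids
$\tau \in \{0.1,\dots,0.8\}$, $\gamma \in \{0.05,0.1,\dots,0.8\}$,
$p \in \{0,0.1,0.2,0.3\}$ and $a \in \{0,0.001,0.005,0.01\}$. All rows share
one sampled collection of seed sets, isolating parameter effects from
seed-set noise.

```{r example, eval = FALSE}
g <- generate_ws(63392, 13, 0.01, rng_seed = 11)
cfg <- protocol_config(n_seed_sets = 10, iterations = 30, rng_seed = 42)
run_protocol(g, model_params("threshold", tau = 0.3), cfg)
#> <protocol_result> threshold | 10 runs x 30 iterations | final infected 19.73% (sd 1.48)
```

## Design choices on genuinely open points

* **One trial per node, not per infected neighbor.** The profile models run a
  single preference trial per susceptible (gated) node per iteration, against
  the *deciding* node's own $\gamma$. The alternative — one trial per
  infected neighbor, an SI-like per-contact scheme — would make exposure
  volume matter in the active model, contradicting its premise that adoption
  depends on interest alone; it also breaks the identity "per-trial adoption
  probability $=1-\gamma$" that anchors the 20%-at-$\gamma{=}0.8$ reading.
* **Blocking per failed trial.** A refuser faces one blocking draw per failed
  trial; under the gate (mixed model) nodes that never pass the threshold can
  never be blocked. Blocking here is refusal-triggered; a pre-run random
  immunization of a fixed fraction is a different mechanism, not implemented.
* **Zero-degree nodes** have infected-neighbor fraction 0, hence are only
  reachable through seeding or spontaneous adoption.
* **Scalar vs per-node parameters.** All experiments use homogeneous scalar
  $\tau$ and $\gamma$; per-node vectors are accepted everywhere for threshold
  or profile distributions drawn by the user.

## Problem sizes, tolerances, limitations

The bundled tests exercise full-size (63392-node) substrates with 10 seed
sets per configuration — the seed-set mean at this size has a standard error
of a few tenths of a percentage point, so nothing is gained by the full 100
sets — and smaller graphs (100–1000 nodes, 10–50 runs) for the stochastic
identities, with 3-standard-error acceptance bands. Monte-Carlo checks of the
per-trial adoption probability use $10^6$ independent one-iteration trials,
batched as disjoint infected–susceptible pairs in one synchronous step.

The generated substrates emulate size and mean degree of a real friendship
graph, not its community structure, clustering, or temporal evolution; a
passing suite shows the models behave as specified on these substrates, not
that any of the three schemes is the right model for a given real cascade.
On the Watts–Strogatz substrate the near-lattice regime makes final coverage
at fixed horizons sensitive to the rewiring convention and rate (we measure
roughly 67% final coverage at $\tau = 0.2$ for an unrewired lattice, ~78% at
$p_{\text{rew}}=0.005$, ~86% at the study's $p_{\text{rew}}=0.01$), so
cross-implementation comparisons should pin down the generator exactly.
Dynamic (temporal) networks and targeted immunization are out of scope.
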