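---
title: "Models and methods behind nudgesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nudgesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nudgesim)
```

## The game

nudgesim simulates a minimal-group token-exchange environment: eight players
in two color groups of four, each holding a starting balance of tokens (30
in the 30-round design, 40 in the 15-round design). Every round each player
must allocate exactly one token to any of the eight players (self included);
each allocation moves one token, so the total balance is conserved. All
allocations become public at the end of the round, and every policy decides
the next round from that public state only — decisions within a round are
simultaneous, so no intra-round information can leak. With a starting
balance at least equal to the number of rounds, no balance can go negative.

Token allocation here is *trivial giving*: tokens carry negligible material
stake, so an allocation is a pure signal of willingness to cooperate, and
withholding one is a signal of distrust.

## Synthetic participants

The humans in the simulation are synthetic. Their allocation policy is a
softmax choice rule over the eight players with utility

$$u_j = b\,[j \in \text{ingroup}] + r\,G_W(j) - e\,[j \text{ ingroup
defector}] + \log(w_{self})\,[j = \text{self}],$$

where $G_W(j)$ counts j's gifts to the focal player over the last $W$
rounds, and an "ingroup defector" is an own-group member whose historical
outgroup share exceeds a threshold $d$. The terms encode the three
behavioral regularities the analysis relies on:

* **ingroup bias** ($b$, default 1.2) — baseline preference for own-group
  targets;
* **reciprocity** ($r$, default 1.5, window $W = 3$ rounds) — short-horizon
  response to recent benefactors, the channel through which outgroup
  altruism by agents can pull human allocations across the group boundary;
* **norm enforcement** ($e$, default 1.0, threshold $d = 0.5$) —
  withholding from own-group members who visibly favor the outgroup, the
  channel that produces withdrawal of cooperation from ingroup agents.

Self-allocation enters with odds weight $w_{self} = 0.3$ and the softmax
temperature is 1. An imitation term exists behind a flag but defaults to
zero, because neither study design we emulate found imitation of the
agents' outgroup altruism.

Under these defaults an agentless population settles into stable ingroup
favoritism: with bias 1.2 the single-round ingroup share is about 0.71, and
the mutual-reinforcement loop of the reciprocity term pushes the realized
per-wave ingroup favoritism of agentless games to roughly 0.85–0.9 in our
runs. The reciprocity spiral also makes the metric drift slowly upward over
waves in the null condition; the directional contrasts the tests assert
(agent conditions below the null at the final wave, steeper wave-1-to-3
decline where agents are present) are therefore computed as
condition-versus-null comparisons, not as absolute declines. These
parameters are a documented calibration of the generator, chosen once; they
are not fitted to any empirical figure, and agreement of the simulation
with published human means is qualitative at best.

What the generator does *not* emulate: individual heterogeneity (all humans
share one parameter set), fatigue or end-game effects, any cognitive
process beyond the utility terms, and the demographic structure of real
samples. Passing directional tests therefore show internal consistency of
the pipeline — agents built to exploit reciprocity do reduce measured
ingroup favoritism in populations that reciprocate — not facts about human
behavior.

Post-game ratings are likewise synthetic plumbing: fairness ratings track
how much of the target's giving favored the rater's group, humanness
ratings are noise around the scale midpoint for every target (emulating
undetected agents), both clamped to the 1–5 scale.

## Nudge agents

**Nonadaptive** agents allocate to a uniformly random member of the
opposite group every round — pure preprogrammed outgroup altruism. They
never self-allocate.

**Adaptive** agents use the cluster hidden Markov model (below). Each round
after a warm-up, the agent refits the model from the full public history,
predicts each outgroup participant's probability of reciprocating, and
allocates uniformly at random among those above the reciprocation
threshold (default 0.5, the natural reading of "likely to reciprocate").
If nobody qualifies, it falls back to a uniformly random ingroup
participant — the behavior that lets it maintain an ingroup reputation.
During warm-up (default: round 1, when there is nothing to learn from) it
allocates uniformly to the outgroup, seeding cross-group reciprocity.
Candidates are restricted to outgroup humans by default; a config flag
admits outgroup agents. Every decision is logged to a per-round trace
(candidate set, chosen recipient, fallback and warm-up flags), so the
ingroup/outgroup split of agent behavior is fully auditable; tests assert
that ingroup allocations coincide exactly with empty-candidate rounds.

## The cluster hidden Markov model

Each player-round is summarized by five features on fixed $[0, 1]$-type
scales (no z-scoring, which keeps the cluster geometry stable across
games): group alignment with the predicting agent, ingroup and outgroup
ties (shares of the player's past non-self allocations by group), wealth
(balance over starting tokens), and reciprocation tendency (share of past
reciprocation opportunities taken). Reciprocation at round $t$ means
allocating to someone who gave to the player within the preceding window
(default 1 round); when nobody gave, the round is an undefined opportunity
and is excluded from tendency denominators rather than counted as a
failure.

Fitting is deliberately count-based:

1. motive centers by k-means on the distinct pooled feature rows (seeded,
   10 restarts, default $K = 4$; $K$ is reduced with a warning when the
   data hold fewer distinct points);
2. state sequences by nearest-center assignment;
3. transition matrix from bigram counts with add-one smoothing (rows are
   exactly stochastic by construction);
4. per-state Bernoulli reciprocation probabilities with Laplace smoothing
   $(s_k + 1)/(n_k + 2)$, so an unobserved state sits at the uninformative
   0.5.

The one-step-ahead prediction for a player currently nearest center $s$ is
$\sum_k T_{sk} e_k$. A forward filter with uniform initialization and
Bernoulli emissions (missing observations carry likelihood 1) gives the
posterior over motives for an observation sequence; it is verified in the
tests against exhaustive path enumeration to $10^{-10}$. There is no
Baum–Welch re-estimation: the clustering fixes the state geometry and the
counts fix the dynamics, which is the simplest construction consistent
with the design and keeps every fitted quantity interpretable and exactly
stochastic. Parameter recovery on a two-motive generator (well-separated
centers, emissions 0.2/0.8, 500 steps) holds emission errors under 0.1 in
median across 20 seeds.

## Designs, metrics and inference

The two shipped designs mirror the study layouts: five conditions
(1:0, 2:0, 1:1, 2:1, 2:2 agents per group) with 10 replicated 30-round
games, and three conditions (null, 2:0, 2:2) with 20 replicated 15-round
games — 280/120 and 360/120 humans/agents respectively. Per-game seeds are
derived from the master seed by a splittable index scheme, so growing a
design never perturbs existing games, and identical master seeds reproduce
logs and metric tables byte for byte.

Metrics follow the study's dependent variables. Ingroup favoritism per
wave is the ratio of a player's ingroup allocations to all of their
non-self allocations within the wave (six-round waves in the 30-round
design, five-round waves in the 15-round design, following the equation's
round bounds where the source material is internally inconsistent about
wave length); a wave with no non-self allocation is undefined and
propagates as missing rather than adopting a 0/0 convention. Agent-produced
events are excluded throughout. Normalized allocation to a target category
divides the allocation count by eligible human allocators per target
(`N` = 3 for ingroup agents, outgroup humans and outgroup agents but 2 for
ingroup humans in a 3-humans-1-agent group, because self-allocation is
removed) and additionally averages per target and per round, which makes
ratios comparable across categories of different sizes and across 30- and
15-round games; under uniform allocation all categories coincide exactly.
The withdrawal contrast is the ingroup-human minus ingroup-agent
normalized ratio within groups holding at least one agent and two humans.

Inference is resampling-based at the game level, the replication unit:
percentile bootstrap confidence intervals for means, and paired sign-flip
permutation tests for wave contrasts (exact enumeration when $2^n$ fits
within the permutation budget, Monte Carlo with add-one correction
otherwise). Mixed-effects modelling of the emitted tidy tables is left to
the user (the tables are one row per game/player/wave, ready for `lme4`);
re-implementing any particular mixed-model table is out of scope here.

## Problem sizes and numerical choices

The shipped tests run the full designs only where exact counting is
asserted; simulation-backed checks use 12 games per condition per
replicate (20 replicates, at least 200 games per directional claim), which
keeps the suite's runtime modest while leaving the directional margins
far from their thresholds. Tolerances: transition-row stochasticity and
weight normalization at $10^{-9}$; oracle equivalence of the forward
filter at $10^{-10}$; frequency checks use 3-sigma binomial bounds. Ties
in nearest-center assignment break toward the lowest state index;
k-means degeneracies are avoided by clustering distinct points only.

## Known limitations

* Synthetic participants are homogeneous and memoryless beyond the
  reciprocity window; none of the published human-subject means are
  reproduction targets.
* The adaptive agent refits from scratch each round; there is no
  cross-game transfer, matching the per-game design but costing a k-means
  fit per round and group.
* The event-log schema is this package's own; mapping a platform export
  onto it requires only renaming columns to the documented schema
  (`round`, allocator/recipient id, group, kind), but no adapter for any
  specific deposit layout is shipped.
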