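# nudgesim

Simulation and analysis of artificial "nudge" agents embedded in
intergroup token-exchange games.

## The problem

In minimal-group exchange experiments, eight players in two color groups of
four repeatedly allocate tokens to one another. Humans show **ingroup
favoritism** — they allocate mostly within their own group — and the
question is whether undisclosed artificial agents that practice **outgroup
altruism** can weaken that favoritism, or whether they are punished as norm
violators. nudgesim provides, for researchers in behavioral game theory and
human–agent interaction:

* a deterministic, seeded engine for the round-based exchange game;
* synthetic human policies with ingroup bias, short-horizon reciprocity and
  norm enforcement (softmax choice over player utilities);
* the two agent designs: a **nonadaptive** agent that gives to a random
  outgroup member every round, and an **adaptive** agent driven by a
  cluster hidden Markov model (CHMM) that predicts which outgroup
  participants are likely to reciprocate and falls back to the ingroup when
  none are;
* the study's dependent variables and resampling inference.

The central metric is ingroup favoritism per wave $w$ of rounds
$[t_{min}, t_{max}]$:

$$IF_w = \frac{\sum_{i=t_{min}}^{t_{max}} IA_i}
              {\sum_{i=t_{min}}^{t_{max}} (IA_i + OA_i)} \in [0, 1],$$

with $IA_i, OA_i$ the indicators of an ingroup/outgroup allocation at round
$i$; self-giving is excluded, and agent-produced events are removed. The
withdrawal-of-cooperation test normalizes allocations to a target category
$x$ as $n_x / N_x$ with $N_x$ the number of eligible human allocators per
target — in a group of 3 humans and 1 agent, $N_x = 3$ for ingroup agents,
outgroup humans and outgroup agents, and $N_x = 2$ for ingroup humans
(self-allocations removed). The CHMM clusters per-player behavioral
features (group alignment, ingroup/outgroup ties, wealth, reciprocation
tendency) into motive states with a count-based transition matrix and
per-state Bernoulli reciprocation probabilities; the one-step prediction
for a player in state $s$ is $\sum_k T_{sk}\,e_k$.

See `vignettes/nudgesim-methods.Rmd` for the full modelling account.

## Worked example

Run a 15-round game with two adaptive agents in group 1:

```r
library(nudgesim)
cfg <- game_config("demo", "2:0", rounds = 15, starting_tokens = 40,
                   agents_per_group = c(2, 0), wave_length = 5, seed = 42)
log <- run_game(cfg, agent_type = "adaptive")
summary(log)
#> Game demo [2:0], 15 rounds, 2 agents
#> Human ingroup allocation share (self excluded): 0.701
#> Final balances:
#> g1a1 g1a2 g1h1 g1h2 g2h1 g2h2 g2h3 g2h4
#>   33   37   43   41   40   44   34   48
```

Tokens are conserved (8 × 40 = 320) and every human allocated once per
round. The per-wave ingroup favoritism and the withdrawal contrast:

```r
aggregate(if_value ~ wave + group, if_series(log), mean, na.rm = TRUE)
#>   wave group if_value
#> 1    1     1    0.700
#> 2    2     1    0.775
#> 3    3     1    1.000
#> 4    1     2    0.650
#> 5    2     2    0.675
#> 6    3     2    0.600
withdrawal_contrast(log)
#>   game_id condition group ingroup_human_ratio ingroup_agent_ratio  contrast
#> 1    demo       2:0     1                 0.5           0.1333333 0.3666667
```

Group 2 (no agents, receiving the agents' outgroup altruism) sits lower
and drifts down; the positive contrast says group 1's humans favored their
human peers over their ingroup agents. A replicated batch with the shipped
Study-2-style design (null / 2:0 / 2:2 conditions), and game-level
inference:

```r
d <- build_study2_design(seed = 1, replications = 12)
b <- run_batch(d, keep_logs = FALSE, ratings = FALSE)
fin <- b$if_table[b$if_table$wave == 3, ]
round(tapply(fin$if_value, fin$condition, mean, na.rm = TRUE), 3)
#>   2:0   2:2  null
#> 0.817 0.523 0.891
w1 <- aggregate(if_value ~ game_id,
                b$if_table[b$if_table$condition == "2:0" &
                           b$if_table$wave == 1, ], mean)
w3 <- aggregate(if_value ~ game_id,
                b$if_table[b$if_table$condition == "2:0" &
                           b$if_table$wave == 3, ], mean)
permutation_wave_test(w1$if_value, w3$if_value)
#> [1] 0.006496752
```

Both agent conditions end below the agentless null at the final wave, and
the wave-1-vs-3 contrast in condition 2:0 is significant under the paired
sign-flip permutation test. `bootstrap_ci()` gives percentile intervals
over games, e.g. `bootstrap_ci(fin$if_value[fin$condition == "null"],
B = 2000, seed = 1)` → `(0.850, 0.929)`.

A thin command-line wrapper is installed at `inst/cli/nudgesim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nudgesim.R", package="nudgesim"))')" \
  --study 2 --seed 1 --replications 20 --out results_s2
```

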