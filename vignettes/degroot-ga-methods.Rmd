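---
title: "Fitting DeGroot opinion-diffusion models with an adaptive genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting DeGroot opinion-diffusion models with an adaptive genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(degrootga)
```

## The model and the estimation problem

The DeGroot model describes opinion diffusion on a social network of $N$
agents as a deterministic linear update

$$X(t+1) = W\,X(t),$$

where $X(t) \in [0,1]^N$ holds the agents' opinions at time $t$ and $W$ is
an $N \times N$ *influence-weight matrix*: $w_{ij}$ is the share of agent
$i$'s updating influence attributed to agent $j$. Each row of $W$ is a
point on the probability simplex ($w_{ij} \ge 0$, $\sum_j w_{ij} = 1$), and
the network's adjacency matrix $A$ (symmetric, binary, with self-links
$a_{ii}=1$) imposes *structural zeros*: $w_{ij} = 0$ wherever $a_{ij} = 0$.

The estimation problem is to recover $W$ from a short panel of opinions
observed at $T$ time steps. Two features make this hard in the settings the
package targets (small sociometric studies in public-health and social
science):

* opinions are not observed on the continuous scale but on an $n$-point
  ordinal (Likert-type) scale, and
* $T$ is small (two to six waves), so the data rarely pin $W$ down
  uniquely.

## Ordinal/continuous transformations

`forward_transform()` divides $[0,1]$ into $n$ equal-width bins and maps
ordinal value $y$ to the centre of bin $y$, $(y - 0.5)/n$;
`back_transform()` maps a continuous opinion $x$ to $\lceil nx \rceil$
(with $x = 0$ mapping to bin 1). Bins are lower-exclusive intervals
$((y-1)/n,\, y/n]$, which is forced by the ceiling rule: a value exactly on
a boundary belongs to the lower bin. On a 5-point scale, ordinal 4 becomes
0.7 and every continuous value in $(0.6, 0.8]$ becomes 4:

```{r}
forward_transform(4, 5)
back_transform(0.7, 5)
```

Ordinal inputs on other labelled scales (say $-2 \dots 2$) should be
shifted to $1 \dots n$ before use. Values of $x$ within $10^{-12}$ below 0
or above 1 — which arise from floating-point error in long products of
row-stochastic matrices — are clamped before binning; anything further out
is treated as an input error, not data.

## The objective function

A candidate $W$ is scored by free-running the model from the
forward-transformed first observation, $\hat X(0) = X(0)$,
$\hat X(t+1) = W \hat X(t)$, and accumulating

$$f(\hat X, X) \;=\; \sum_{i=1}^{N} \sum_{t=0}^{T-1}
  B\!\left(\hat x_i(t), x_i(t)\right)\,\bigl|\hat x_i(t) - x_i(t)\bigr|,$$

where $B(\cdot,\cdot)$ is the absolute deviation of the two values' bins
(`bin_deviation()`). Continuous deviation is penalised *only* when the
prediction lands in the wrong bin, so $f = 0$ exactly when every predicted
opinion matches the observation on the ordinal scale — a "perfect solution"
which, importantly, need not equal the generating $W$. The per-agent
summands (the *gene-level* fitness of row $i$, `gene_fitness()`) add up to
the total exactly and drive the gene-swapping operator.

Seeding the prediction at the observed first wave (rather than one-step-
ahead predictions from every wave) matches how the synthetic data are
generated and makes the $t=0$ terms vanish identically. Because $B$ is
integer-valued, the objective is discontinuous and non-differentiable in
$W$ — the reason a population-based direct-search method is used rather
than gradient descent.

## The adaptive genetic algorithm

A *chromosome* is a candidate weight matrix; a *gene* is one of its rows.
`fit_degroot()` evolves an odd-sized population (default 21) built by
`initialize_population()`: random row-stochastic matrices (Unif(0,1)
weights rescaled row-wise) plus one identity matrix, a prior that agents
mostly weigh themselves. Each generation applies, in order:

1. **Selection with elitism.** The lowest-objective chromosome (ties to
   the lowest index) is exempted from the disruptive operators.
   **Gene swapping** is attempted between the elite and the rest: for each
   row position, the strictly fittest donor gene (judged inside its own
   chromosome's predicted trajectory) replaces the elite's gene; all such
   swaps are applied at once and kept only if the elite's total objective
   strictly improves, otherwise everything reverts.
2. **Blending.** The remaining even population is paired uniformly at
   random. Per row, with probability $p_b$, a blending factor
   $\beta \sim$ Unif(0,1) replaces the paired rows by their convex
   combinations $\beta B_i + (1-\beta) C_i$ and
   $(1-\beta) B_i + \beta C_i$ — row sums and fixed values survive
   automatically.
3. **Crossover.** Per row, with probability $p_c$, the evolvable values of
   the row are reshuffled uniformly among their positions. This is a
   deliberately drastic exploration move; sum-to-one is preserved because
   the multiset of values is.
4. **Mutation.** Per row, with probability $p_m$, one evolvable weight
   gets Gaussian noise $\varepsilon \sim N(0, \sigma^2)$ and the row is
   repaired: negative values clamp to 0; values above the available mass
   $1 - w_{\text{fixed}}$ clamp to it with all other evolvable weights set
   to 0 (the only operator that *creates* boundary "edge-case" rows); if
   the selected weight held the entire mass the excess is spread evenly;
   otherwise the other weights are rescaled multiplicatively to restore
   the exact row sum. The printed description of that rescaling constant
   in the source literature is typographically garbled; the package uses
   the unique scaling that restores the unit row sum,
   $(1 - w_{\text{fixed}} - w^*) / (\text{previous sum of the others})$.
5. **Survival.** Parent $j$ and offspring $j$ are compared; the fitter
   (ties to the parent) attempts gene swapping with the loser as sole
   donor, and the winner survives alongside the elite.

**Adaptation.** A single stagnation counter tracks consecutive generations
in which the elite objective failed to improve by more than `min_improve`;
it resets to zero on improvement. Whenever the counter reaches a positive
multiple of a threshold `iter*`, the corresponding control parameter is
multiplied by its factor and clamped: $p_b$ grows towards `maxb` while
$p_c$, $p_m$ and $\sigma$ shrink towards their floors. The same counter
drives reintroduction: every `iterr` stagnant generations the worst
non-elite chromosome is replaced by an elite clone (default) or an
identity matrix. Early generations therefore explore aggressively —
including the simplex boundary, which mutation rule (b) reaches — and long
stagnation shifts the population towards local refinement of the elite.

**Stopping.** The run ends when the elite objective is at or below
`min_dev` (default 0, i.e. a perfect ordinal solution), *checked only at
every 1000th generation*, or at `max_iter` (default 100,000). Elapsed time
is recorded per 1000-generation block.

### Determinism and tie-breaking

With a `seed`, a run is bit-reproducible. All randomness flows through R's
RNG in a fixed documented order (initial population; then per generation:
pairing permutation, per-row blending coin and beta, per-row crossover
coin and shuffle, per-row mutation coin, position and noise). Every tie
breaks deterministically: lowest index for elites and donors, the
incumbent parent in survival, the highest index for the worst chromosome
replaced at reintroduction. The per-generation loop is compiled code, but
it consumes the same RNG stream as R, which is what the operator-level
oracle tests in the package exploit.

### Hyperparameters

`ga_control()` exposes all 22 settings and three grouped presets that tile
the space: `prob_sigma` (initial $p_b, p_c, p_m, \sigma$; low / medium /
high), `min_max` (clamping bounds; minimal / moderate / extreme) and
`mult_factor` (adaptation factors; slow / moderate / rapid), plus a single
`iter` applied to all five stagnation thresholds. The defaults — 21
chromosomes, medium, moderate, moderate, `iter = 200` — are the
recommended starting configuration; the calibration machinery below exists
precisely to show how performance depends on them. The one setting that
deserves care is `iters` (equivalently the shared `iter`) together with
`sigma`: too-large values force long boundary exploration and can degrade
parameter recovery even among runs that find perfect solutions, while
`factors` near 1 softens an aggressively small `iters`.

## The synthetic-data generator

`simulate_diffusion()` reproduces the study conditions the algorithm was
calibrated under, and is the package's test bed:

* a connected Erdős–Rényi network with edge probability
  $p = d/(N-1)$, so the expected degree equals the target $d$; draws are
  rejected until connected (which implies minimum degree 1 for $N \ge 2$),
  then self-links are added. Rejection, not repair, was chosen as the
  least interventionist reading of "reject disconnected networks"; note
  that conditioning on connectivity biases the realised mean degree
  slightly upward (for $N = 4, d = 2$ the exact conditional mean degree is
  2.154, by enumeration of all 64 graphs), which the tests account for;
* self-weights $w_{ii} \sim$ Beta$(\kappa\mu, \kappa(1-\mu))$ with target
  mean $\mu = 0.5$ and concentration $\kappa = 4$ (Beta(2,2)), remaining
  row weights Unif(0,1) on the neighbours rescaled to $1 - w_{ii}$ — a
  ground truth that almost surely contains no boundary rows, i.e. is
  *biased against edge cases*;
* initial opinions $X(0) \sim$ Unif(0,1), a deterministic DeGroot
  trajectory over $T$ steps, and elementwise ordinal observation on $n$
  bins.

What the generator does *not* emulate about real panels: measurement
error beyond binning, missing agents or waves, opinion scales without
interval properties, and directed or weighted influence. Passing
recovery tests on this generator therefore demonstrates the estimator
works when the model is true and fully observed — not that the DeGroot
model fits any particular real network.

## The calibration harness

`study_design()` builds the crossed factor grid the hyperparameters were
calibrated on: $N \in \{4, 20, 50\}$, $d \in \{2, 5, 9\}$ (cells with
$d \ge N$ are infeasible and dropped), $T \in \{2, 3, 6\}$,
$n \in \{5, 7, 10, 20, 30\}$, population sizes $\{5, 21, 51, 99\}$, the
three levels of each preset group, and stagnation thresholds
$\{200, 1000, 5000\}$ — 34,020 feasible cells. `run_study()` runs each
(sub)sampled cell for a number of replicates, each with a freshly
generated network, weight matrix and dataset, and records per run the
objective, solved flag, generations (in thousand-generation blocks),
elapsed seconds and the recovery RMSE

$$\mathrm{RMSE}_{rec} = \sqrt{\tfrac{1}{P} \textstyle\sum_{a_{ij}=1}
  (w_{ij} - \hat w_{ij})^2},$$

over the $P$ non-structurally-zero positions. Per-run seeds derive
deterministically from the base seed, cell id and replicate, so the whole
results table is a pure function of the design; subsampling is by cell
(not by run) to preserve replicate structure, and a partially written CSV
is resumed rather than recomputed. `summarize_study()` reduces the records
to the headline aggregates: proportions of runs solved within the first
1000-generation block and unsolved at the cap, and RMSE / speed summaries
grouped by stagnation level, initial-control level, time steps and
population size.

The full 10-replicate factorial (340,200 runs) is a cluster-scale
computation. The package's own checks run a seeded uniform subsample of a
few hundred cells with one replicate each, which is sufficient for the
aggregate proportions at a few percentage points' precision; the vignette
and tests state the sizes they use.

Two directional properties of the design are checked with matched-seed
pairs rather than the full grid: more observed waves improve recovery
(T = 6 vs T = 2 at $N = 4$), and a short stagnation threshold beats a long
one. The second comparison is only informative where the threshold can
fire at all: on easy instances every run finds a perfect solution before
stagnation reaches even 200 generations, and the fits are then
bit-identical across `iter` levels. The check therefore uses a harder
instance ($N = 20$, $T = 6$, $n = 30$) with high initial $\sigma$, where
prolonged boundary exploration under `iter = 5000` measurably degrades
recovery relative to `iter = 200`.

## A worked example

```{r}
sim <- simulate_diffusion(n_agents = 4, mean_degree = 2, n_steps = 6,
                          n_bins = 10, seed = 1)
fit <- fit_degroot(sim$observed, sim$adjacency, n_bins = 10, seed = 1)
glance(fit)
recovery_rmse(sim$weights, fit$weights, sim$adjacency)
```

`tidy(fit)` returns the estimated weights one entry per row for further
dplyr work, and `autoplot(fit)` shows the elite-objective trace with the
adapting control parameters.

## Numerical choices and limitations

* **Row-sum tolerance.** Validation accepts row sums within $10^{-9}$ of
  1; the operators restore exact unit sums analytically (blending and
  crossover preserve them, mutation renormalises), so drift stays at
  machine precision even over $10^5$ generations.
* **Degenerate rows.** Rows with a single evolvable position are skipped
  by crossover and mutation (there is nothing to permute and no other
  weight to absorb a perturbation); isolated agents get self-weight 1.
* **Infeasible design cells.** Target degree at or above $N$ cannot be
  realised and such cells are dropped with a message rather than clamped
  to a complete graph.
* **Perfect-solution multiplicity.** With few waves and coarse scales
  many weight matrices reproduce the observed bins exactly; the algorithm
  returns one of them, and recovery RMSE — not the objective — is the
  meaningful yardstick against simulated truth. On real data no such
  yardstick exists.
* **Elapsed times** are wall-clock measurements of compiled code on the
  host machine; they are recorded for relative comparisons (e.g. across
  population sizes) and are not comparable across machines.
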