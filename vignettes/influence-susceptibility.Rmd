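---
title: "Inferring influence and susceptibility from cascade data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring influence and susceptibility from cascade data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spreadis)
library(dplyr)
```

## The model

spreadis studies peer-to-peer information contagion on a *diffusion
network*: a directed graph whose edge $i \to j$ exists iff at least one
recorded spreading event (a reshare/retweet of $i$'s content by $j$) links
the two users. The generative assumption is the product transmission model:
the probability that a piece of content propagates from $i$ to $j$ is

$$p_{ij} = A_{ij}\, I_i\, S_j,$$

where $A$ is the network adjacency, $I_i \in [0,1]$ is $i$'s **influence**
(how strongly $i$'s reshares convert neighbors) and $S_j \in [0,1]$ is
$j$'s **susceptibility** (how easily $j$ is converted). Influence here is a
*local* trait — the per-contact conversion strength — not the ability to
trigger global cascades; the prediction pipeline below asks to what extent
the local traits forecast the global outcome.

## The estimator

From a multi-cascade event log we estimate the per-edge *contagion rate*

$$\omega_{ij} = \frac{\#\{\text{pieces } j \text{ reshared from } i\}}
                     {\#\{\text{pieces } i \text{ participated in}\}},$$

a plug-in estimate of $p_{ij}$ conditional on $i$'s activation. Row and
column sums of $\omega$ over the edge set give the outgoing and incoming
contagion rates $\hat f_i = \sum_j A_{ij}\omega_{ij}$ and
$\hat g_j = \sum_i A_{ij}\omega_{ij}$. Summing the model equation the same
way and eliminating $p$ yields the coupled nonlinear system

$$\hat I_i = \frac{\hat f_i}{\sum_j A_{ij}\hat S_j}, \qquad
  \hat S_j = \frac{\hat g_j}{\sum_i A_{ij}\hat I_i}.$$

Intuitively, a node is highly influential if it converts neighbors at a
high rate *even though those neighbors are hard to convert* — the
denominator discounts the rate by the audience's susceptibility — and
symmetrically for susceptibility. Two design decisions about $\omega$ are
worth making explicit:

* the numerator counts only reshares *explicitly attributed* to $i$
  (`parent_id == i`), matching platforms where the source is mentioned;
* the denominator counts every piece $i$ participated in, whether as
  cascade root or as a resharer. Treating roots as participation is a
  choice the data does not force; it is the inclusive reading of "pieces
  $i$ reshared" and keeps denominators positive for root-only users.

## The iteration and its numerics

The fixed-point system is solved iteratively by `run_is()`. Two schemes are
provided:

* **alternating** (default, Gauss–Seidel): update $\hat I$ from the current
  $\hat S$, then $\hat S$ from the *new* $\hat I$;
* **jacobi**: both updates from the previous iterate, the map as usually
  printed.

The two schemes share exactly the same fixed points, but the simultaneous
scheme has a genuine pathology: on a single edge it hops between two gauge
images of the solution forever (from init $(1,1)$ on an edge with
$\omega = 0.5$ the iterates alternate between $(0.5, 0.5)$ and $(1, 1)$).
The alternating scheme damps this mode structurally and converged on every
random instance we generate in the test suite (residual $<10^{-8}$ on 100
random digraphs of up to 100 nodes at tolerance $10^{-10}$); the Jacobi
scheme is retained behind `scheme = "jacobi"` for fidelity, and its 2-cycle
is caught by the `max_iter` guard with a non-convergence warning.

Remaining numerical choices, with defaults:

* **Initialization**: all ones for both vectors. The system determines the
  pair only up to the gauge map $(I, S) \to (cI, S/c)$ (per weakly
  connected component), so any positive initialization reaches the same
  ray; rescaling the initial pair by $(c, 1/c)$ rescales every Jacobi
  iterate by exactly $(c, 1/c)$, and leaves the normalized alternating
  output unchanged. This covariance is asserted in the tests.
* **Gauge convention**: `gauge_normalize()` rescales $\hat I$ to unit mean
  over its positive entries. Every quantity reported downstream (rankings,
  correlations, edge products $\hat I_i \hat S_j$, the TIS feature) is
  gauge-invariant, so the convention is cosmetic.
* **Convergence**: maximum relative change of any active score below
  `tol = 1e-8` (tests and benchmarks use `1e-10`), cap 10,000 iterations,
  optional damping (`0.5` for hard instances; default 0).
* **Zero handling**: nodes with $\hat f_i = 0$ are pinned at
  $\hat I_i = 0$ (and symmetrically for $\hat S$); they stay in other
  nodes' denominator sums with value zero, matching the equations read
  literally. Since every node with $\hat f_i > 0$ has an out-edge with
  $\omega > 0$, its denominator contains a strictly positive
  susceptibility, so no active denominator can vanish — asserted on every
  run.
* **Residual**: `fixed_point_residual()` reports the maximum relative
  violation $|1 - (\hat f_i/\sum_j A_{ij}\hat S_j)/\hat I_i|$ over active
  nodes (and the symmetric term), a gauge-invariant figure that is 0 at an
  exact fixed point.

`brute_force_fixed_point()` is an independent oracle for small instances:
damped Levenberg–Marquardt root-finding in log-space from many restarts,
with the gauge removed by pinning the lowest-id active node per weak
component. The tests require that the iteration and the oracle agree on all
edge products to $10^{-6}$ across 100 random connected digraphs of up to 5
nodes.

```{r single-edge}
rates <- contagion_rates(tibble::tibble(from = "i", to = "j", omega = 0.5))
tidy(run_is(rates))
```

## The simulator

`simulate_cascades()` implements independent-cascade semantics: one root
per piece, and each newly active node makes exactly one activation attempt
per still-inactive out-neighbor, succeeding with probability $I_i S_j$. One
attempt per edge per cascade is the reading under which $\omega$ estimates
$p_{ij}$ conditional on the source's activation; repeated attempts would
inflate effective transmissibility. Traits live in $[0,1]$ by construction
(beta marginals coupled by a Gaussian copula to a target Spearman
correlation, default $-0.5$), so products never need clipping and the
binomial oracles in the tests are exact. Timestamps are integer
breadth-first steps offset by per-cascade start times, which makes windowed
experiments possible; piece ids are unique per cascade.

What the generator does *not* emulate: homophily (which confounds contagion
estimates in observational data), content heterogeneity, bursty or
circadian timing, follower-graph structure distinct from the diffusion
graph, and users resharing a piece more than once. Passing the synthetic
benchmarks therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to these real-data
complications.

### A censoring effect worth knowing about

In dense, highly active regimes the $\omega$ estimator is *censored*: if
$j$ was already activated by another parent before $i$ fired, the edge
$i \to j$ cannot record an event for that piece, although the piece counts
in $i$'s denominator. The bias compresses susceptibility estimates for
easily-activated nodes, and it does not vanish with more cascades. On the
standard reconstruction benchmark below (supercritical, mean cascade size
about 55) influence recovery is immune (Spearman $\rho \approx 0.97$) but
susceptibility recovery plateaus around $\rho \approx 0.89$–$0.93$
depending on the realization. This is a property of the estimator's
definition, which we keep faithful to its source rather than re-weighting.

## Standard benchmarks and problem sizes

Two fixed configurations, exposed as functions so that tests, scripts and
this vignette run the same conditions (component seeds derive from one base
seed as `seed`, `seed + 1`, `seed + 2`):

* `benchmark_recovery()` — reconstruction: ER digraph with $n = 300$, mean
  out-degree 6, beta(2,2) traits at Spearman $-0.5$, 2000 cascades,
  tolerance $10^{-10}$. The acceptance checks require both recovery
  correlations $\ge 0.9$, degradation $< 0.15$ after dropping 30% of
  non-root events, and the reconstructed scores to reproduce the planted
  anticorrelation (top-decile influence/susceptibility overlap below the
  $q^2$ independence baseline).
* `benchmark_prediction()` — superspreader prediction: $n = 2000$ users,
  two windows of 25,000 cascades each, fully persistent traits, beta(2,4)
  marginals. The marginals put spreading in the *subcritical* regime
  ($R_0 \approx 0.6$): cascade sizes are then governed by the root's local
  traits, as in empirical reshare data where cascades are overwhelmingly
  small. In a supercritical regime every successful cascade reaches
  roughly the same giant size, the superspreader label degenerates into
  take-off luck, and no feature — behavioral or structural — can predict
  it; that regime is the wrong test bed for a prediction task. 25,000
  cascades give each user about 12 initiations per window, enough for
  "mean initiated-cascade size" to reflect ability rather than single-draw
  noise.

These sizes run the whole validation suite in a couple of minutes on one
core while leaving comfortable margins on every acceptance bound.

## Network statistics and the randomized null

`centralities()` provides in/out-degree, PageRank (damping 0.85, on the
recorded edge direction; the reversed convention is an option) and the
k-core index on total degree. All correlation statistics are Spearman
correlations restricted to pairs where both values are nonzero — zero
scores mark nodes outside the estimator's support, not minimal trait
values — and are reported as `NA` (never 0) when fewer than three
qualifying pairs remain.

Significance is assessed against a degree-preserving null:
double-edge swaps that carry each edge's $\omega$ (and event count) with
its source stub, with the full IS estimation re-run on every rewired
instance, and an add-one two-sided empirical p-value. Carrying rates with
source stubs preserves each node's $k^{in}$, $k^{out}$ *and* $\hat f_i$
exactly; consequently any statistic channelled through outgoing rate and
degree alone — such as a $k^{out}$–$\hat I$ correlation driven by
$\hat f/k^{out}$ — is largely reproduced by the null and is *not*
identifiable against it. Planted-signal validation therefore uses an
assortativity statistic, $\rho(\hat I, \hat S^{out}_{nn})$, whose signal
lives entirely in who links to whom: `benchmark_planted_assortativity()`
wires high-influence nodes preferentially to high-susceptibility targets,
and the null detects the plant at $p \le 0.05$ with 99 replicates.

The four stylized facts about influence and susceptibility (anticorrelated
traits, similar peer-susceptibility across influence levels, influence
heavier-tailed than susceptibility, influencer clustering) are qualitative;
`stylized_facts()` operationalizes each with an explicit statistic and
baseline (defaults: top/bottom decile, and for the tail comparison a
symmetric gauge that equates the two score means before counting
exceedances of twice the common mean). Each check reports the continuous
value next to its baseline rather than a bare pass/fail.

## The prediction pipeline

For a window pair $(d_t, d_{t+1})$, `compute_features()` runs the full
estimation chain on $d_t$ and emits, per user: the IS scores; the
neighbor aggregates $TS_i = \sum_j A_{ij}\hat S_j$,
$TI_i = \sum_j A_{ij}\hat I_j$ and the IS total score
$TIS_i = \hat I_i \cdot TS_i$ (the expected high-contagion outflow, an
exact algebraic identity asserted in the tests); the contagion rates
$\hat f, \hat g$; the four centralities; and the user's past success (mean
initiated-cascade size in $d_t$). `label_superspreaders()` marks the top
$z\% = 5\%$ of the cohort by mean initiated-cascade size in $d_{t+1}$,
with deterministic (score-descending, id-ascending) tie-breaking; the
cohort is the training window's node set, and absent users score 0.

The behavior-IS model uses all five IS-based predictors (any can be
dropped via `drop_features`); behavior-CR uses the two contagion rates;
the structural model the four centralities; the combined model everything
plus past success. The classifier is a 500-tree random forest with class
weights inversely proportional to class frequency and impurity-based
importances, evaluated on a held-out stratified 30% of the cohort (the
train/test protocol is not dictated by the estimation theory; in-sample
evaluation is available for comparison). Metrics are AUPRC — computed as
average precision, whose random-ranker baseline is the positive rate — and
precision at $k$ with $k$ the number of held-out positives, where it
coincides with recall. A seeded uniform ranking is the random baseline.

```{r predict-demo, eval = FALSE}
bench <- benchmark_prediction(seed = 1)
glance(train_eval(bench$features, bench$labels,
                  feature_set = "behavior_is", seed = 1))
```

On the standard prediction benchmark the behavior-IS model averages AUPRC
about 0.32 over ten evaluation seeds against a positive rate of 0.05
(random baseline about 0.06), with the structural model in between — the
qualitative ordering the method is designed to exhibit. These numbers are
recomputed, not asserted, by `scripts/acceptance.R` and the test suite.

## Known limitations

* The $\omega$ censoring bias above: susceptibility estimates compress in
  dense/highly-active regimes.
* Scores are identified per weakly connected component only up to gauge;
  cross-component score comparisons inherit the iteration's implicit
  scale. All shipped statistics are rank- or product-based to stay
  gauge-safe, and estimation networks of interest are typically one giant
  component.
* The null model preserves $\hat f$ by construction; statistics driven by
  outgoing totals require a differently-designed null.
* No homophily correction: in observational data, trait estimates absorb
  whatever correlated exposure the diffusion network encodes.
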