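---
title: "Cost-efficient incomplete stepped wedge designs: models, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-efficient incomplete stepped wedge designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swce)
```

## The design problem

A stepped wedge cluster randomized trial assigns clusters to S sequences;
each sequence starts under the control condition and switches to the
intervention in a staggered, randomized period, so that with the standard
schedule sequence s is under control in periods 1..s and under
intervention in periods s+1..T, with T = S + 1. In the complete design
every cluster is measured in every period. Measurement is often the
dominant burden and cost driver, and cells far from a sequence's treatment
switch contribute little information to the treatment effect estimate.
`swce` searches for *incomplete* designs — designs with some
sequence-period cells unmeasured — that retain adequate power at a much
lower total cost.

## Statistical model and variance computation

We assume a continuous outcome with repeated cross-sectional sampling
(each participant is measured once) and a constant cluster-period size m.
The outcome for participant i in period j of cluster k is

$$Y_{kji} = \mu + \beta_j + X_{kj}\theta + \gamma_{kj} + \epsilon_{kji},$$

with categorical period effects $\beta_j$, treatment indicator $X_{kj}$,
cluster-period random effects $\gamma_k \sim N(0, \tau^2 R)$ and
independent errors $\epsilon_{kji} \sim N(0, \sigma^2_\epsilon)$. The
within-cluster correlation structure is set by `corr_spec()`:

* **discrete-time decay**: $R_{jj'} = r^{|j-j'|}$, so the correlation
  between two participants' outcomes in the same cluster is
  $\rho\, r^{|j-j'|}$, where $\rho$ is the within-period intracluster
  correlation (ICC) and $r$ the cluster autocorrelation (CAC);
* **block-exchangeable**: constant between-period correlation $\rho r$;
* **exchangeable**: $\rho$ everywhere, the $r = 1$ special case of both.

**Variance normalization.** Power depends only on the standardized effect
size and correlation parameters, not on the raw outcome scale, so the
package fixes the total variance $\tau^2 + \sigma^2_\epsilon = 1$; i.e.
$\tau^2 = \rho$, $\sigma^2_\epsilon = 1 - \rho$. `power_spec()`'s
`effect_size` is therefore directly the standardized effect.

`treatment_variance()` evaluates the GLS variance of $\hat\theta$ on
**cluster-period means**, whose covariance for a cluster observed in
periods $J$ is $\tau^2 R_{[J,J]} + (\sigma^2_\epsilon / m) I$. This
collapse is mathematically exact for the model above; the test suite
verifies it against a brute-force individual-level GLS oracle (the full
participant-by-participant covariance matrix) to 1e-10 relative tolerance
on all small designs. Two details matter for incomplete designs:

* **Gaps widen correlation distance.** The decay correlation is evaluated
  at the original period labels, so two measurements separated by an
  unmeasured period are correlated as lag 2, not lag 1.
* **Globally unobserved periods.** Period-effect columns for periods that
  no sequence measures are dropped before inversion; keeping them would
  make the period information matrix structurally singular. This is a
  re-labelling of time for the fixed effects only — correlation distances
  are preserved.

Power uses the normal approximation for the two-sided Wald test,
$\Phi(\theta_d/\sqrt{\mathrm{var}(\hat\theta)} - z_{1-\alpha/2})$. A
t-based correction is deliberately not offered: there is no agreed
degrees-of-freedom choice for multi-period (let alone incomplete) stepped
wedge designs, so the normal reference is used throughout.

**Estimability.** A design is estimable when the reduced period-effect
information matrix has reciprocal condition number above 1e-10 and the
residual treatment information exceeds 1e-12. These thresholds separate
structural singularity (e.g. a single sequence whose treatment indicator
is confounded with period effects, or no observed treatment contrast at
all) from float noise; the matrices involved are at most T x T, where
condition numbers near these thresholds do not arise for real designs.
Non-estimable designs raise a dedicated `swce_not_estimable` condition
rather than a numerical error.

## Cost model

`total_cost()` implements a seven-parameter linear cost model
(`cost_spec()`): per-cluster cost c, per-cluster condition-implementation
costs k and k', per-participant costs p and p', and restart costs g and
g'. A *gap* is a maximal run of unmeasured periods in a sequence with at
least one measured period on both sides; leading and trailing unmeasured
runs are not gaps because nothing restarts after them. Each gap incurs one
restart cost per cluster.

**Gap condition attribution.** A gap could be attributed to the condition
before or after it. The package attributes each gap to the condition of
the first measured period *after* the gap, because the restart cost is the
cost of resuming data collection — retraining happens on the resumption
side. With this rule the package reproduces the worked counts of the
motivating example (e.g. a sequence measuring control in period 1,
intervention in periods 2–3, pausing in 4–5 and resuming intervention in
period 6 has one intervention gap and no control gaps).

k and k' are charged once per cluster that measures at least one period
under the respective condition, not per period. Costs are unitless
non-negative reals and no rounding is applied anywhere, so integer inputs
give integer-exact totals.

## The greedy search and the optimal design

`cost_efficiency()` is $CE(D) = 1/(\mathrm{var}_D(\hat\theta)\, C(D))$;
`relative_cost_efficiency()` compares to a reference design.
`greedy_removal_search()` starts from the complete design and, at each
iteration, evaluates the removal of every currently observed
sequence-period cell, skipping removals that destroy estimability, and
commits the one yielding the highest CE. It stops when no observed cell
can be removed without losing estimability, so the final trace member is
minimally viable along the greedy path (not necessarily the globally
smallest viable design — no such claim is made). `select_optimal()` then
returns the trace member with maximal RCE among those with power at least
`min_power`. The reference design itself is not a member of the searched
space: if no reduced design qualifies, the selection is empty and the CLI
reports "use the complete design" (exit status 3).

Design choices worth knowing:

* **Tie-break.** Candidates whose CE is within 1e-12 relative of the
  maximum are resolved in favor of the smallest sequence index, then the
  smallest period index. This makes traces byte-reproducible; in
  principle a printed endpoint could depend on tie order, which is why the
  rule is logged in every `run_log.txt`.
* **Skip, don't stop.** A removal that destroys estimability removes that
  *candidate*, not the search: the iteration continues with the remaining
  candidates. Stopping at the first non-estimable candidate would end
  traces far too early (corner cells become non-removable long before the
  design is minimally viable).
* **Per-sequence caching.** All clusters on a sequence are exchangeable,
  so per-sequence information contributions are computed once and weighted
  by the cluster count, and a candidate evaluation only recomputes the one
  modified sequence. This is a pure speed optimization (exact); it brings
  the 210-cell example below from minutes to seconds.
* **No iteration cap.** The loop is bounded by the observed-cell count of
  the reference design, not by a formula in T; the search also works when
  the starting design is already incomplete.

## Correlation uncertainty: the superset procedure

ICC and CAC are rarely known at the planning stage. `superset_search()`
takes a `correlation_grid()` (the Cartesian product of plausible ICC and
CAC values), runs the greedy search and optimal selection at every grid
point, and forms the **superset design**: the union of the observed cells
of all per-point optima. Since adding cells can only decrease the
variance, the superset has at least `min_power` power at every grid point
that contributed an optimum — that is the procedure's guarantee. The
result also carries per-cell inclusion counts (how many grid optima
contain each cell), so users who prefer an intersection-style or
thresholded variant can construct one; the costed and powered design
reported by the package is the union.

Grid points at which even the complete design is under-powered cannot
contribute (no incomplete design can outperform the complete one in
power); they are reported in `skipped_points` with a warning and excluded
from the union, leaving the user to revise the trial configuration for
those scenarios.

## Parameters at a glance

| Parameter | Meaning | Default |
|---|---|---|
| `icc` ($\rho$) | within-period intracluster correlation | required, [0, 1) |
| `cac` ($r$) | cluster autocorrelation (decay per period) | 1 (exchangeable) |
| `effect_size` ($\theta_d$) | standardized effect to detect | required |
| `alpha` | two-sided test size | 0.05 |
| `min_power` | power constraint for design selection | 0.80 |
| `cluster_period_size` (m) | participants per measured cluster-period | required |
| costs c, k, k', p, p', g, g' | currency units of the user's choice | 0 |

## What the packaged examples emulate — and what a green test shows

The packaged configurations (`inst/extdata/`) encode two desk-scale
planning problems: a 5-sequence, 37-cluster pharmacy trial (m = 7,
differential participant costs, modest intervention restart cost) and a
larger 14-sequence, 15-period design with one cluster per sequence,
m = 50, and either an expensive intervention-side restart cost or none.
These are *configurations*, not data: every number the package produces is
an analytic design-stage quantity (variance, power, cost), so there is no
sampling noise anywhere and all results are exactly reproducible. A green
acceptance run therefore establishes that the implementation reproduces
the benchmark arithmetic and search endpoints — it does not validate the
mixed-model assumptions themselves (correlation structure, constant
cluster-period size, cross-sectional sampling) against any real dataset.

Known limitations, intentionally out of scope: t-distribution power with
degrees-of-freedom corrections; closed- or open-cohort sampling; unequal
cluster-period sizes; linear-in-time period effects; transition periods;
gap-length-dependent restart costs; cluster-period-level (as opposed to
sequence-period-level) removal; and exhaustive or metaheuristic searches
of the $2^{S\times T}$ design space.

## A complete run

```{r example, eval = FALSE}
design <- sw_complete(5, c(8, 7, 7, 7, 8), 7)
corr   <- corr_spec("discrete_time_decay", icc = 0.05, cac = 0.95)
costs  <- cost_spec(cost_per_cluster = 2500,
                    participant_cost_intervention = 140,
                    participant_cost_control = 80,
                    restart_cost_intervention = 230)
pw     <- power_spec(effect_size = 0.26)

trace <- greedy_removal_search(design, corr, costs, pw)
opt   <- select_optimal(trace)
opt$metrics

sup <- superset_search(design,
                       correlation_grid(c(0.01, 0.05, 0.1), c(0.8, 0.9, 0.95)),
                       costs, pw)
sup$cost
```
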