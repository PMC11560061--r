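---
title: "Methods: optimal test designs for measuring ability growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal test designs for measuring ability growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the design criteria, the
optimizers, and the numerical and design decisions behind the package's
defaults. It states the *methods*; the quantitative behavior of the package
is established by the test suite and by `scripts/acceptance.R`, not by claims
made here.

## Measurement model

Items are dichotomous and follow the two-parameter logistic (2PL) model: an
examinee with ability $\theta$ answers an item with discrimination $a > 0$
and difficulty $b$ correctly with probability

$$p(\theta) = \frac{1}{1 + e^{-a(\theta - b)}}.$$

The item's Fisher information is $I(\theta) = a^2\, p(\theta)\,
(1 - p(\theta))$, maximal at $\theta = b$ with value $a^2/4$, and a form's
test information function (TIF) is the sum of its items' information.
`items()`, `prob_correct()`, `item_information()` and `test_information()`
implement these primitives; probabilities use `plogis()` and information is
computed as $a^2 t/(1+t)^2$ with $t = e^{-|a(\theta-b)|}$, which is exact and
overflow-free for arbitrarily extreme abilities.

## Growth design and variance expressions

A `growth_design()` holds three item roles: items unique to form 1, anchor
items common to both forms, and items unique to form 2. Form 1 is
administered to $N_1$ examinees at the first time point, form 2 to $N_2$
examinees at the second; the anchors link the two scales so the mean growth
$d = \mu_2 - \mu_1$ is estimable (a NEAT layout).

Treating the maximum-likelihood ability estimates as asymptotically unbiased
with variance $1/\mathrm{TIF}(\theta)$, and the two samples as independent,
the variance of the estimated mean growth **conditional on the realized
abilities** is

$$\operatorname{Var}(\hat d) =
  \frac{1}{N_1^2}\sum_{j=1}^{N_1}\frac{1}{\mathrm{TIF}_1(\theta_{j,1})} +
  \frac{1}{N_2^2}\sum_{j=1}^{N_2}\frac{1}{\mathrm{TIF}_2(\theta_{j,2})},$$

implemented by `asymptotic_var_growth()`. For growth at a percentile $p$,
the corresponding expression is $1/\mathrm{TIF}_1(\theta_{1p}) +
1/\mathrm{TIF}_2(\theta_{2p})$ at the two populations' $p$-th quantiles
(`asymptotic_var_percentile()`).

## Design criteria

At design time the future abilities are unknown, so the criteria replace the
sums over examinees with weighted sums over discretized ability
distributions. Each population ($N(-d/2, 1)$ and $N(+d/2, 1)$) is
discretized onto $l$ equidistant points spanning mean $\pm$ `half_width`
(default 4 ability units, beyond which a unit normal carries mass
$< 10^{-4}$), with weights proportional to the normal density and normalized
to sum to one per grid (`make_normal_grid()`). The growth criterion
(`crit_growth()`) is then

$$\Psi_d = \sum_j \frac{w_{j,1}}{\mathrm{TIF}_1(\theta_{j,1})} +
           \sum_j \frac{w_{j,2}}{\mathrm{TIF}_2(\theta_{j,2})}.$$

Because the constant factors $1/N_k^2$ rescale the objective without moving
its argmin, the criteria omit them; with one-point grids the criterion equals
$N \cdot \operatorname{Var}(\hat d)$ exactly, which the tests verify.

Percentile criteria (`crit_percentile()`) evaluate the forms at the
population quantiles with density-proportional weights standardized *jointly
across both sums* (total mass one). Combined objectives
(`build_case_objective()`) assign each component criterion equal mass and
renormalize the total to one:

* **Case 1** — the growth criterion over $l = 100$-point grids;
* **Case 2** — case 1 plus the 25th/75th-percentile criterion;
* **Case 3** — the 25th/50th/75th-percentile criterion alone;
* **Case 4** — two groups sharing the forms, the second with both grids
  shifted by `group_shift` (default 0.25).

Weight-standardization choices (per-grid mass for the growth criterion,
joint mass for percentiles, equal mass per component with a final
renormalization) only rescale the objective within each case; they are fixed
so criterion values are comparable across runs of the same case.

### Optimum-in-average weights

If the population mean itself is uncertain, $x \sim N(\mu, \sigma^2)$, the
design weights become the prior-integrated density
$\int f(\theta \mid x)\, f(x \mid \mu, \sigma)\,dx$, which for unit-variance
populations has the closed form of an $N(\mu, 1 + \sigma^2)$ density
(`in_average_density()`, verified against numerical quadrature in the
tests). The resulting weights have heavier tails than the ordinary ones,
hedging the design against misspecified growth.
`uncertainty_ratio_experiment()` measures the effect: per replicate it draws
lognormal discriminations, optimizes once with ordinary and once with
in-average weights, and compares the two designs' asymptotic standard
deviations at a range of *true* growth values.

## Continuous optimizer: particle swarm

`pso_minimize()` is a standard-2007-style particle swarm: inertia
$1/(2\ln 2)$, cognitive and social coefficients $0.5 + \ln 2$, and a random
informer topology in which each particle informs any other with probability
`proportion_informed` (default 0.2), regenerated after any iteration without
global improvement. Positions leaving the box $[-6, 6]$ are clamped with the
offending velocity component zeroed. The run stops when the global best
improves by less than `convergence_tol` (default $10^{-10}$) over a
50-iteration window. Defaults (swarm size 200, dimension $n_1 + n_c + n_2$)
are the settings used by the study harnesses; the search space is the packed
difficulty vector in role order (unique-1, common, unique-2), with
discriminations held fixed at the scenario's `a_level`.

The criterion evaluation is the hot path: for a swarm of 200 over 75
difficulties and 200 grid components, every iteration needs 200 × 75 × 200
information terms. The compiled evaluator exploits that the grid abilities
and discriminations are fixed across a run: it precomputes
$E_{ij} = e^{-a_i \theta_j}$ once, so each candidate needs only $n$
exponentials ($g_i = e^{a_i b_i}$), with $p(1-p) = u/(1+u)^2$ for
$u = E_{ij} g_i$ and a large-$u$ guard. The R and compiled paths are checked
against a scalar double-loop oracle to $10^{-12}$ on randomized designs.

## Discrete optimizer: simulated annealing

`sa_select()` assembles role-assigned forms from an `item_pool()`. A move
swaps the occupant of one uniformly chosen slot (keeping its role) with one
uniformly chosen unselected item; improvements ($\Delta \le 0$) are always
accepted, uphill moves with probability $e^{-\Delta/t}$. The temperature
starts at $t_0 = 100$ (uphill acceptance $\approx e^{-0.01}$ for
$\Delta = 1$, i.e. close to 1) and cools geometrically by $\alpha = 0.8$
after each epoch of 5000 moves, for 100 epochs (`sa_temperatures()` exposes
the schedule). `greedy_refine()` then runs the same neighborhood for 100,000
moves accepting strict improvements only, as a no-further-improvement check;
`exhaustive_select()` enumerates small pools as a testing oracle.

Two implementation decisions matter for testability:

* **Fixed draw protocol.** Every proposed move consumes exactly three random
  draws (slot, replacement, acceptance uniform) whether or not all are used,
  so annealing at a vanishing temperature and greedy descent follow
  *identical* move streams from the same generator state — a property the
  tests assert directly.
* **Incremental evaluation.** For `design_criterion()` objectives the
  engine precomputes each pool item's information at every grid component
  and maintains the two forms' TIF vectors across swaps, making a move
  $O(l)$ instead of $O(n\,l)$; the incremental and full evaluations are
  cross-checked, and the returned `criterion_value` is always a full
  re-evaluation of the best-ever selection.

## Synthetic pool generator

`generate_synthetic_pool()` emulates a calibrated pool of dichotomous items
at the scale of a large operational assessment: 248 items by default, with
discriminations following a lognormal shape truncated to $[0.40, 1.90]$
(constants solved once so the truncated mean is 1.14) and difficulties a
symmetric truncated normal on $[-1.56, 1.60]$, mean-centered. Sampling is
inverse-CDF, so pools are bit-reproducible from the seed. These defaults are
study conditions, not tuning knobs: they were fixed before any selection
experiment was run. `center_difficulties()` makes an external pool's scale
comparable to designs optimized around zero.

## Monte-Carlo validation

`mc_validate_variance()` checks the variance expression end to end: draw $N$
abilities per population **once**, then repeatedly simulate 2PL responses,
estimate every ability by maximum likelihood (`estimate_abilities()`, a
damped, clamped Newton iteration on the strictly concave log-likelihood),
form $\hat d = \bar\theta_2 - \bar\theta_1$, and compare the empirical
variance across replicates with `asymptotic_var_growth()` *at the drawn
abilities*. Abilities are drawn once because the asymptotic expression is
conditional on the abilities; redrawing them each replicate would add the
between-sample variance of the means ($\approx 2/N$) to the empirical side
only.

The validation design used in the acceptance test spans difficulties well
beyond the bulk of the ability distribution (unique items spread over
$[-4.2, 4.2]$). That choice is deliberate: finite-length ML scoring attains
the information bound only where the form is informative, and for abilities
outside a narrow form's difficulty span the estimator's variance measurably
exceeds $1/\mathrm{TIF}$, which would confound a check of the variance
*formula* with the estimator's small-sample behavior.

## Reproducibility plumbing

All experiment harnesses derive per-run seeds from their scenario keys with
a multiplicative-congruential mix, so a record is identical whether produced
alone or inside a sweep. Scripted runs (`read_run_config()`, the `run_*`
functions, and the command-line script in `inst/cli/`) are driven by a
schema-checked yaml configuration — unknown keys are rejected by name, and
the growth distance has *no* default — and every run writes its resolved
configuration with a content hash next to its outputs.

## Limitations

* The variance expressions treat the two administrations as independent
  cross-sectional samples; longitudinal designs with repeated examinees
  (covariance between $\hat\mu_1$ and $\hat\mu_2$) are out of scope.
* Discriminations are inputs, not decision variables: the continuous
  optimizer places difficulties for given `a_level`s, and the pool selector
  chooses among fixed calibrated items.
* The criteria assume unit-variance normal populations; other ability
  distributions require supplying custom grids via `ability_grid()`.
* The particle swarm offers no optimality certificate; stability under
  repeated random starts (`stability_analysis()`) is the practical check,
  and the annealer is validated against exhaustive enumeration only at
  small pool sizes.
* Percentile-growth variances use the same ML-estimator asymptotics as the
  mean; quantile estimation error in finite samples is not modeled.
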