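---
title: "Modelling quantitative-trait evolution on trees with fossil tips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling quantitative-trait evolution on trees with fossil tips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossiltrait)
```

## The model

Ancestral states of a continuous trait inferred from extant species alone
are bounded by the observed range and carry no information about
directional change. Fossil tips break both limitations: a tip observed at
its true (non-zero) age anchors the trait process in the past, which makes
a drift term identifiable. `fossiltrait` models a single continuous trait
(log body mass in log-grams, mean latitude in degrees, ...) on a rooted,
time-calibrated phylogeny whose tips may end before the present.

Along a branch of duration $t$ (Myr) the trait follows Brownian motion
with trend,

$$v_{i+t} \sim \mathcal{N}\!\left(v_i + \mu_0 t,\; \sigma^2 t\right),$$

where $\sigma^2$ is the rate of trait evolution (trait units$^2$ Myr$^{-1}$)
and $\mu_0$ the trend (trait units Myr$^{-1}$). Both parameters may shift
across clades: a *shift* is anchored at a non-root node and applies to the
branch subtending that node and to all descendant branches until overridden
by a nested anchor. Rate and trend shifts are anchored independently, so a
tree with $n$ tips admits up to $n-2$ shifts of each kind.

Rather than marginalizing internal states through a variance–covariance
matrix (cubic in the number of tips), the likelihood is *augmented*: states
at all internal nodes are explicit variables, and the likelihood is a
product of univariate normal densities over branches. This is what makes
run time linear in tree size.

## The sampler

One MCMC iteration performs, in order:

1. **Birth–death sweep over shift configurations.** Model search follows a
   continuous-time birth–death process on the set of shifts, run for one
   unit of virtual time per iteration. Births arrive at rate 1: a kind
   (rate/trend) is chosen with probability 1/2, an anchor uniformly among
   eligible non-root nodes, and a value from the birth proposal
   (exponential with mean equal to the current background rate; normal with
   SD 1 for trends). Each existing shift dies at a rate equal to the
   likelihood ratio without/with the shift — "without" meaning the clade
   reverts to the parameter of the anchor's parent — times, under the
   default `stephens` policy, the ratio of the birth-proposal density to
   the model-prior density of the removed value. With a Poisson(1) prior on
   the number of shifts and birth rate 1, the remaining prior factors
   cancel exactly, so a useless shift dies at rate $\approx 1$ and a shift
   that improves the fit by $\Delta$ log-units dies at rate $e^{-\Delta}$.
   The `likelihood_only` policy (the bare ratio) is available for
   comparison; it coincides with `stephens` whenever the birth proposal
   equals the value prior.
2. **Multiplier updates of every rate class** ($\sigma^2$ background and
   each shift value), with the log-uniform multiplier
   $m = e^{\lambda(u - 1/2)}$, $\lambda = 2\ln d$, $d = 1.5$, and Hastings
   ratio $m$.
3. **Sliding-window updates of every trend class** (symmetric uniform
   increments), when trends are enabled.
4. **Sliding-window update of the root state** under a flat prior, so its
   acceptance is a pure likelihood ratio.
5. **A Gibbs sweep over all unobserved internal states.** The full
   conditional of a state given its parent and children is the product of
   three normal densities and is itself normal; each of the three terms
   uses its own branch's resolved rate and trend, which leaves the
   conjugacy intact. Nodes are visited in child-before-parent order so tip
   information propagates rootward within a sweep.

Priors: exponential on every $\sigma^2$ class with rate
$1/(\mathrm{var(tips)}/\mathrm{tree\ height})$ (weakly informative and
scale-matched; the data-independent constant is configurable), normal
$(0, 10)$ on every trend class, Poisson(1) on the shift count, flat on the
root state.

### Identifiability and the no-fossil default

On an ultrametric tree the trend only shifts all tip means jointly with the
root state; the two form a ridge and $\mu_0$ is unidentifiable. When the
input tree has no fossil tips the package therefore fixes $\mu_0 = 0$ and
disables trend-shift births (override with `trendEnabled = TRUE`).

### Tuning choices

* Multiplier $d = 1.5$; no adaptation, for reproducibility.
* Sliding-window widths: $2\,\mathrm{sd(tips)}$ for the root state and
  $\mathrm{sd(tips)}/\mathrm{height}$ for trends. The trend window is
  divided by the tree height because the trend has units of trait per Myr:
  an unscaled window makes trend moves almost never (or always) accept on
  Myr-scale trees. Both constants were set so that acceptance rates fall
  inside (0.1, 0.8) on problems of the size of the platyrrhine data
  (~100 tips, height ~45 Myr).
* One birth–death sweep of one unit of virtual time per iteration, capped
  at 100 events (a cap hit aborts the sweep with a warning and keeps the
  configuration).
* Initial state: homogeneous model with $\sigma^2 =$ var(tips)/height,
  $\mu_0 = 0$; internal states by rootward child-averaging of observed
  values; non-finite starts are re-jittered up to 10 times.
* Burn-in 25% of samples in all posterior summaries.

### Numerical details

* All death rates are computed in log space and capped at $e^{50}$.
* Updates that leave branch variances unchanged (trend, root, Gibbs means)
  avoid recomputing log-determinant terms, which is what makes the
  compiled sampler fast; the R reference implementations (`treeLogLik`,
  `gibbsSweep`, `bdmcmcStep`, ...) compute the same quantities naively and
  are cross-checked against the compiled chain in the tests.
* Zero-length branches (sampled ancestors) contribute no density term; an
  observed value on a degree-2 node, or on a tip at the end of a
  zero-length branch, becomes that node's fixed state.
* Extant/fossil classification uses a relative age tolerance of
  $10^{-6}\times$ tree height, because posterior tree samples carry
  floating-point jitter at the present.
* Posterior-mode shift counts break ties toward the smaller count.

## The simulator

`simulateTree()` runs a forward constant-rate birth–death process from a
single lineage, conditioned on reaching a target number of living tips; the
present is drawn uniformly within the first holding interval at the target
count, which avoids a zero-length cherry at the stopping event. Extinct
lineages are kept and become fossil tips at their true extinction times —
there is no preservation model, so "20 fossils" means 20 uniformly chosen
true extinction events (`subsampleFossils()`); incomplete present-day
sampling is uniform tip retention (`subsampleExtant()`). Traits are then
evolved along the *analysis* tree. Pruning first and simulating second is
distributionally identical to the reverse order because Brownian motion
with trend is Markov and closed under subtree induction, and it keeps true
internal states aligned with the analyzed nodes.

Study conditions (`makeScenarioGrid()`): birth 0.2 and death 0.1 per
lineage per Myr, which give crown ages around 35–55 Myr for 50–200 extant
tips — the scale of the platyrrhine radiation — and ample extinct lineages;
$\sigma^2 \sim U(0.1, 1)$; trended scenarios use
$\mu_0 = \pm U(0.2, 1)\sqrt{\sigma^2}$; shifted scenarios anchor shifts at
clades holding 20–45% of the tips with rate factors $\times 8$ or $\div 8$
and trend offsets $\pm\sqrt{\sigma^2}$. The clade-size floor reflects an
evidence calculation: a rate *decrease* by factor $f$ contributes only
$\tfrac12(\ln f - 1 + 1/f)$ expected log-evidence per phylogenetic
contrast (vs $\tfrac12(f - 1 - \ln f)$ for an increase), which must clear
the $\log(2n-2)$ uniform-anchor penalty for the shift to be detectable in
principle. Even so, individual down-shift replicates can carry genuinely
marginal evidence, and the posterior mode then (correctly) prefers fewer
shifts — parameter-recovery error rates in the shifted scenarios should be
read with that in mind.

What the simulations do **not** emulate about real data: fossilized
birth–death preservation (fossil ages here are true extinction times, not
sampled occurrences), measurement error on trait values, within-species
variation, topological/temporal uncertainty in the tree (supported at the
analysis level via `runReplicates()` over a posterior tree sample), and
non-Brownian processes. Passing validation therefore demonstrates correct
inference *under the model*, not robustness to these violations.

## Validation harness

`runValidation()` simulates replicates under a scenario, runs the sampler,
and reports the study's metrics: MAPE of the posterior-mean background
rate, MAE of the posterior-mean trend, the regression $R^2$ (squared
Pearson correlation) between true and posterior-mean internal states, and
the frequency with which the posterior-mode shift count equals the truth.
The regression form of $R^2$ is used deliberately: when the trend is
misspecified (fixed to zero on trended data), state estimates acquire a
systematic depth-linear offset; the regression $R^2$ still measures how
much of the true variation the estimates track, whereas the
$1-\mathrm{SS_{res}}/\mathrm{SS_{tot}}$ form collapses below zero under any
systematic bias.

Posterior means after 25% burn-in serve as the point estimates throughout —
the conventional Bayes estimate under squared loss.

A typical scaled-down check (a few minutes; the suite and the acceptance
script use 10–15 replicates and chains of 150k–400k iterations to stay
inside ordinary desktop budgets, versus 100 replicates and 5M-iteration
chains for a full study):

```{r validation, eval = FALSE}
grid <- makeScenarioGrid()
v <- runValidation(grid$sc2, nReplicates = 15,
                   settings = chainSettings(iterations = 400000,
                                            sampleEvery = 400),
                   seed = 1)
v
#> accuracyReport [sc2], 15 replicates:
#>   MAPE(sigma2) = 0.116   MAE(mu0) = 0.035
#>   mean R2(ancestral states) = 0.975
#>   shift-count recovery = 100.0%
```

## Known limitations

* The trend acts on calendar time exactly as written in the branch
  equation; no separate "evolutionary time" clock is offered.
* No measurement-error term on tip values.
* Single trait only; no OU or multi-optimum models.
* Marginal-likelihood estimation and convergence auto-diagnostics are out
  of scope; traces are returned for external inspection.
* With weak shift evidence the posterior-mode shift count is conservative
  by construction (Poisson(1) prior, ties toward fewer shifts).
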