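---
title: "Models for dyadic behavior sequences: methods and conventions"
author: "dyadseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models for dyadic behavior sequences: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadseq)
```

This vignette is the package's account of the statistics it implements: the
data model, each estimator and its assumptions, the tunable parameters and
their defaults, the numerical conventions, and — importantly — what the
synthetic-data checks do and do not establish about real data.

## 1. Data model

The observational unit is a *dyad* (two distinguishable members, e.g., a
couple) observed by interval sampling: per interval, two binary codes record
whether partner A showed behavior A (e.g., stress communication) and whether
partner B showed behavior B (e.g., dyadic coping). A `dyad_pair` therefore
holds two aligned 0/1 vectors plus optional dyad-level covariates; a
`dyad_dataset` is a set of pairs with unique ids.

Conventions:

* **Intervals are 1-based** everywhere; a transition is `(t-1) -> t` for
  `t = 2..T_obs`, so a `T`-interval dyad has `T - 1` transitions.
* **Dropout** (a dyad leaving before the end) must appear as a *shared
  terminal* run of missing cells in both streams; internal gaps and
  one-sided missingness are rejected as coding errors rather than imputed.
  At least 2 observed intervals are required.
* **State expansion** joins the two streams into one sequence over the fixed
  four-letter alphabet *(none, A-only, B-only, both)*; `collapse_states()`
  is its exact inverse and is used by the simulators.

### Descriptive statistics

`describe()` reports, per interval, the distribution over the four states
and its Shannon entropy normalized by `ln 4` so the plot range is `[0, 1]`
(0 = all dyads in the same state, 1 = uniform). With dropouts, per-interval
denominators use only the dyads still under observation; this keeps each
column a proper distribution but makes late intervals noisier. Transition
counts are reported raw (not rescaled for shortened sequences): a count is
comparable across dyads only at equal `T_obs`, which the print method does
not hide.

`frequency_correlation()` correlates the per-dyad *counts* of 1-intervals.
Counts and proportions give the same correlation only at equal lengths, so a
warning is emitted when lengths differ.

## 2. Aggregated logit actor–partner model

For one dyad and a chosen outcome partner, the 4×2 `transition_table()`
cross-tabulates the joint state at `t-1` (rows ordered (A=yes,B=yes),
(yes,no), (no,yes), (no,no)) against occurrence of the outcome behavior at
`t`. The saturated logit with effect-coded lagged predictors
(+1 shown / −1 not shown),

$$\ln\frac{P}{1-P} = \beta_0 + \beta_{actor}\,own_{t-1} +
\beta_{partner}\,other_{t-1} + \beta_{ixn}\,own_{t-1}other_{t-1},$$

has a closed-form ML solution because the model is exactly identified: with
row log-odds $L_s$, $\beta_0$ is their mean and the other coefficients are
the matching ±1 contrasts divided by 4. `fit_saturated_logit()` implements
this closed form; on all-positive tables with constant 0 it agrees with
iteratively reweighted logistic regression to numerical precision (tested to
1e-8).

**Zero frequencies.** Empty cells make the logit inestimable. The default
policy adds a constant of 0.5 to *all eight cells of every table* — applying
it only to problem tables would make dyads incomparable, and the uniform
constant is exactly what reproduces published single-case fits from their
printed counts. The alternative `"drop"` policy excludes dyads with any
empty cell and fits the rest with constant 0. Both policies are biased in
known directions: the constant attenuates all coefficients toward zero
("conservative"), dropping selects against rare-behavior dyads.

`aggregate_logit()` averages each coefficient across dyads and tests the
mean against zero with a one-sample t test (df = n−1), reporting
`exp(mean)` as an odds ratio. `apim_summary()` runs both outcome directions
and adds paired t tests on the per-dyad differences. Group comparisons
(`compare_logit_groups()`) use Welch's unequal-variance t test with
Welch–Satterthwaite df; the equal-variance variant was deliberately not
chosen because cluster sizes and spreads typically differ.

**What "recovery" means for this estimator.** On simulated data the
across-dyad mean converges to the *expectation of the per-dyad estimator*,
not to the generating β: at 48 intervals the 0.5 constant plus small row
counts attenuate the actor effect by about 0.05 at β = 0.5 (measured at
n = 2000 dyads; the direction is toward zero, never a sign flip). The test
suite therefore checks (i) consistency against that estimand, measured by an
independent large-n run, and (ii) an explicit attenuation bound of 0.1
against the generating values. A naive "mean within the 95% CI of β" check
would fail for a perfectly correct implementation, because the t-interval
estimates the estimand, not β.

## 3. Multilevel logistic actor–partner model

`build_long()` turns each dyad into `2(T_obs − 1)` records: for every
`t >= 2`, one record per member with outcome `dv` (that member's behavior at
`t`, coded occurrence = 1), effect-coded lagged own behavior `ae`, lagged
partner behavior `pe`, and a member dummy `sex` (0 = reference member, the
partner whose behavior is stream B). The model is

$$\mathrm{logit}\,P(dv=1) = \gamma_0 + \gamma_1 ae + \gamma_2 pe +
\gamma_3 ae\,pe + \gamma_4 sex + \gamma_5 ae\,sex + \gamma_6 pe\,sex +
\gamma_7 ae\,pe\,sex + \text{dyad random effects},$$

fitted by Laplace-approximated marginal ML (`lme4::glmer`) with an
unstructured covariance among the requested random terms. The outcome is
coded occurrence = 1 throughout: the opposite printed convention sometimes
seen would flip every sign and contradict the standard interpretation of
positive actor effects as behavior persistence.

* `select_random_structure()` compares candidate random-effect subsets by
  BIC; the default ladder is none, intercept, +actor, +partner,
  +interaction.
* **BIC sample size** defaults to the number of dyads (the level-2 units
  whose count governs random-effect information); `n_type = "records"`
  switches to the observation count. Free parameters are the 8 fixed effects
  plus `q(q+1)/2` covariance entries.
* `sex_specific_effects()` returns the reference member's (γ0…γ3) and the
  other member's (γ0+γ4, …, γ3+γ7) effects with delta-method SEs from the
  fixed-effect covariance; it agrees with refitting under reversed reference
  coding to 1e-6.

Recovery checks for the fixed effects use the *joint* 95% Wald confidence
region (χ², df 8): eight marginal 95% intervals jointly miss the truth
about a third of the time even for a perfect estimator, so the marginal
check would be miscalibrated as a deterministic test. Known caveats:
level-2 SEs are biased downward below ~50 dyads, and Laplace (rather than
adaptive quadrature) is the approximation contract — small numerical
differences from other software are expected.

## 4. Markov family on the expanded states

`fit_markov()` is exact ML: transition matrix = row-normalized pooled
transition counts, initial distribution = empirical first states,
log-likelihood includes the initial terms. A never-visited prior state
leaves its row `NaN` with a warning rather than silently uniform.
Conditional actor/partner effects are read off the transition matrix as
column sums of "states containing the behavior" from the appropriate prior
row — e.g., the actor effect of A without prior B is
`p(A-only|A-only) + p(both|A-only)`.

`fit_hmm()` is Baum–Welch EM with scaled forward–backward, pooled over
sequences (grouped by length and vectorized across dyads). Theoretical
restrictions enter as a fixed-zero transition mask — e.g., an absorbing
"coped" state — which multiplicative EM updates preserve bit-exactly.
`fit_mixture()` is latent-class EM over per-dyad sufficient statistics
(first state + 16 transition counts); a one-class mixture equals the basic
Markov fit exactly, which the tests assert to 1e-8.

Numerical conventions:

* EM stops when the relative log-likelihood change is below 1e-6 or at 500
  iterations; the log-likelihood trace is stored and asserted non-decreasing
  at every iteration.
* Default 10 random restarts (Dirichlet(1) initializations respecting
  masks), seeded; the best restart is reported along with all restart
  log-likelihoods.
* Canonical reporting order: HMM latent states by descending initial
  probability, mixture classes by descending weight (ties: lexicographic
  first transition row), so label switching cannot change reported tables.
* Free-parameter counts: basic Markov 15; HMM `(K−1) + (unmasked − K) +
  3K`; mixture `(K−1) + 15K`.
* **BIC sample size** is the total number of observed intervals (the
  likelihood includes the initial terms, and this matches the magnitude of
  BICs reported for 64 × 48 designs, ≈ 5000); `fit_markov()` offers
  `n_type = "dyads"` as the alternative. Models handed to `compare_bic()`
  carry a fingerprint of their data; comparing fits on different data is an
  error.

## 5. Optimal-matching clustering

Substitution costs come from the TRATE rule on a basic Markov model fitted
to the same data: `cost(i,j) = 2 − p(j|i) − p(i|j)`, zero diagonal, so
states that frequently follow each other are cheap to exchange (0 when each
always follows the other, 2 when never consecutive). The indel cost
defaults to 1.0 — one insertion/deletion counts as one operation. The edit
distance is a standard dynamic program (C++); sequences of unequal length
are compared as-is, so dropouts are absorbed by indels and may legitimately
form their own cluster — this behavior is reproduced, not corrected.

Clustering is Ward's minimum-variance criterion via the Lance–Williams
recurrence on *squared* dissimilarities (`hclust(method = "ward.D")` on
`D^2`), with merge heights reported on the squared scale. The number of
clusters is chosen by the mean silhouette width over `k = 2..min(8, n−1)`
(singletons contribute width 0); a mean above 0.51 flags "reasonable
structure". The flag is advisory only: a solution with a weak coefficient
is reported, never auto-rejected, and the returned diagnostics (dendrogram,
merge-height scree, classical MDS coordinates) are the corroboration tools.
`agreement()` scores two labelings by the best one-to-one label matching
(exact over permutations, up to 6 groups); `covariate_association()` is the
point-biserial correlation with a t-based two-tailed p.

## 6. Design helpers

`est_freq()` simulates the per-dyad transition table expected under a
planned design by i.i.d. multinomial draws from the expected cell
probabilities — the table-level view, matching the helper's inputs, rather
than a chain simulation (available conceptually but off by default, and the
difference is immaterial at the cell-count level). One draw per *transition*
(`T − 1`) is the default; `draws = "intervals"` uses `T` draws for
arithmetic phrased in observation counts. `est_time()` inverts it:
doubling-plus-bisection for the smallest `T` whose expected problem-cell
count is below a tolerance, with a common seed across `T` so the search sees
a monotone curve; structurally empty cells make a zero-cell tolerance below
their count infeasible and raise an error.

`sample_size_t()` computes power exactly from the noncentral t distribution
(one-sample ncp `d√n`; two-sample ncp `d√(n/2)` with df `2n−2`) and returns
the smallest integer n reaching the target; the suite verifies minimality
(`power(n−1) < target ≤ power(n)`). For a strong one-sample effect
(d = 0.80) this computation gives N = 15; a commonly quoted value of 18 does
not verify against the noncentral-t calculation and is not reproduced.
`sample_size_correlation()` uses the Fisher-z approximation
`((z_{1−α/2}+z_{pow})/\mathrm{atanh}\,r)^2 + 3`, which can differ by ±1
from exact-distribution tables (85 vs 84 at r = 0.30).

## 7. Synthetic-data generators: what they emulate, what they don't

The generators produce study-shaped data — two interdependent binary streams
per dyad, by default full-length sequences with an optional geometric
dropout that is off because no dropout mechanism is part of any model — from
each model family: `simulate_markov` (first-order chain over joint states),
`simulate_hmm` (latent chain + categorical emissions, returning the latent
traces for checks), `simulate_mixture` (classes drawn from the weights, true
labels returned), and `simulate_logit_apim` (both behaviors Bernoulli given
the lagged effect-coded predictors, conditionally independent given `t−1`
since the model specifies lagged terms only; optional shared normal
perturbations of the coefficients per dyad emulate dyad-level random
effects). All are bit-reproducible given a seed, via an isolated RNG scope.

Reference conditions used across tests mirror a medium couple study: 64
dyads × 48 intervals, transition structure with strong persistence of the
"none" and "both" states, most dyads starting in "both". Parameter-recovery
runs scale up only as far as precision requires: ~5000 transitions for the
basic Markov (±0.03 elementwise), 500 dyads × 48 for the HMM with an
absorbing mask (±0.03 after canonical ordering), 200 dyads × 48 for the
two-class mixture (hard-label accuracy ≥ 0.8 after matching), 300 dyads for
the aggregated logit, 200 dyads for the GLMM.

Passing these checks shows the estimators invert their own generative
models at realistic sizes. It does *not* show that real interaction data
satisfy stationarity, first-order dependence, conditional independence of
the two behaviors given the previous interval, or missingness completely at
random — on real data those are substantive assumptions the models impose,
and the BIC comparisons (basic vs hidden vs mixture) are the only in-package
instrument for questioning them.

## 8. Known limitations

* No semi-Markov durations, covariate-dependent transitions, multi-channel
  emissions, or mixture-HMM hybrids; no latent Markov variant for very short
  sequences (hidden Markov fits need long sequences).
* The multilevel model cannot give each member separate random effects (the
  double-entry formulation is out of scope); no autoregressive residual
  structure.
* No multiple imputation for dropouts; all models assume MCAR dropout.
* `est_freq`/`est_time` cover exactly two dichotomous behaviors (the 4×2
  table); richer codings need proportionally more intervals and are not
  simulated.
* Single-case inference for low-frequency tables (Monte-Carlo tests) is not
  provided; the 0.5-constant route is the supported small-sample device.
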