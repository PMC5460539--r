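---
title: "Common and marginal hazard ratios in matched-pair cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common and marginal hazard ratios in matched-pair cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairhr)
```

## The model and the closed form

A 1:1 matched cohort follows $n$ pairs, each with one exposed ($e = 1$)
and one unexposed ($e = 0$) member.  Event times may be cut short by
drop-out or by the administrative end of follow-up $\tau$, so for member
$e$ of pair $k$ we observe $X_{ke} = \min(T_{ke}, U_{ke}, \tau)$ and the
event indicator $Y_{ke}$.  If a common hazard ratio across pairs is
plausible, the natural model is the Cox model stratified on the pair,

$$\lambda_{ke}(t) = \lambda_{k0}(t)\, e^{\beta e},$$

with an unrestricted baseline hazard $\lambda_{k0}$ per pair.  Each pair
contributes to the stratified partial likelihood only through the
ordering of its two observed times and the event status of the earlier
one.  Classifying pairs by that ordering gives nine observable types
(`classify_pairs()`); a pair contributes $e^\beta/(1+e^\beta)$ when the
exposed member is first *and* has an event, $1/(1+e^\beta)$ when the
unexposed member is, and nothing otherwise.  Writing $G$ and $H$ for the
two contributing counts, the partial likelihood is
$\{e^\beta/(1+e^\beta)\}^G \{1/(1+e^\beta)\}^H$, maximized at

$$\widehat{HR} = G/H, \qquad
  \widehat{\mathrm{var}}\{\log(G/H)\} = 1/G + 1/H,$$

with the score test of $\beta = 0$ equal to $(G-H)^2/(G+H)$
(`common_hr_pmle()`, `stratified_logrank()`).  These closed forms are
exact restatements of the iteratively fitted pair-stratified Cox model;
the package's own Newton engine reproduces them to machine precision,
which is tested routinely.

The same counts yield a concordance interpretation: among comparable
pairs — those whose shorter-observed-time member had an event —
$\max(G,H)/(G+H)$ estimates the probability that the member from the
higher-hazard arm fails first, and its odds equal the common hazard
ratio (`pair_c_statistic()`).  The estimate remains consistent when
censoring is independent of the event time conditionally on pair and
exposure, even when censoring rates differ between arms; this is the
property the simulation study exercises.

## Tie conventions and degenerate inputs

Recorded ties are resolved by fixed conventions rather than tolerances:

* event vs. censoring at the same time: the event is taken to precede,
  so the pair contributes (type 3 or 4).  This matches the usual
  risk-set convention that a subject censored at $t$ is still at risk
  for events at $t$.
* both members censored at the same time: type 7 before $\tau$, type 9
  at a finite $\tau$.  Because type 7 absorbs these ties with the
  exposed member listed first, the cosmetic type-7/8 split is not
  symmetric under relabeling the arms; $G$ and $H$ are.
* both events at the same time: the distinguished code 0.  Under the
  Breslow approximation such a stratum contributes
  $e^\beta/(1+e^\beta)\cdot 1/(1+e^\beta)$, identical to one type-1
  plus one type-2 pair, so the pair adds 1 to both $G$ and $H$.  Efron
  or exact tie handling is deliberately not implemented: with strata of
  size two the Breslow form is what keeps the $G/H$ identity exact.

Times are compared for exact equality after parsing; ties should be a
feature of the recorded data, not a floating-point accident, so no
tolerance-based tie detection is applied.

Boundary data raise errors rather than infinities: $H = 0$ (or $G = 0$)
is a diverging one-sided estimate, $G = H = 0$ carries no information.
The Monte-Carlo harness treats these as failed replicates (below).

## The Cox engine

`fit_cox()` maximizes the Breslow partial likelihood by Newton–Raphson
with step-halving, supporting strata, positive case weights and a
cluster-robust sandwich variance.  Numerical choices:

* convergence when the gradient max-norm falls below `tol` (default
  1e-8), at most 50 iterations, with the log-likelihood forced
  non-decreasing by halving the step;
* a separation guard aborts when any coefficient passes 15 on the log
  scale (monotone likelihood);
* risk sets contain subjects with time $\ge t$; sums over risk sets are
  grouped cumulative sums over (stratum, time)-sorted rows, so tied
  subjects share one denominator;
* the sandwich variance aggregates score residuals within clusters with
  no small-sample correction, the standard choice in this literature.

The engine exists so that the closed form, the score test and the
unstratified comparator all come from one audited code path; the test
suite cross-checks every configuration (stratified, weighted, clustered,
tied) against the independent `survival` package and against brute-force
likelihood scans.

## Comparator estimators

Two person-time estimators of the common HR are provided for
completeness.  The conditional-Poisson MLE solves
$\sum_k (Y_{k1}X_{k0} - HR\,Y_{k0}X_{k1})/(X_{k0} + HR\,X_{k1}) = 0$,
a strictly decreasing estimating function; the root is found on the
$\log HR$ axis with an expanding bracket from $[-10, 10]$, a scale-free
parameterization on which the function is monotone.  The
Mantel–Haenszel rate ratio replaces the weights by $1/(X_{k0}+X_{k1})$;
the two estimating functions coincide exactly at $HR = 1$, so the
estimators agree to first order near the null and drift apart in
proportion to the distance from it — the property tests measure exactly
that, averaging the gap over replicate null cohorts rather than
asserting a per-draw bound that the proportional gap would violate for
unlucky draws.  Neither estimator ships a variance: no standard form
exists for the MH rate ratio in this setting, and inventing one was out
of scope.

## The simulation design

`draw_cohort()` generates pair $k$ with a shared frailty
$\gamma_k \sim N(0, \sigma^2)$ ($\sigma = 1$ by default) and exponential
event times with rates $\lambda_0 e^{\gamma_k + \beta e}$,
$\lambda_0 = 1$.  Censoring patterns:

* **independent**: exponential with a common rate $c \in \{1, 2, 4\}$
  in the study grid;
* **conditional**: exponential with rate $e^{\gamma_k + \alpha e}$,
  giving a censoring-rate ratio $e^\alpha \in \{0.25, 1, 4\}$ between
  arms.  The rate is exponentiated because a Normal $\gamma_k$ makes the
  literal sum $\gamma_k + \alpha e$ negative with positive probability;
  the exponential form is the only reading that yields a valid rate for
  every pair while preserving the labeled rate ratios, and it is the
  package's documented choice.

Simulations run without an administrative $\tau$ (purely random
censoring); a finite $\tau$ is available for users.  Replicate $i$ of a
scenario draws its seed from the master seed through a fixed Lehmer
step, so individual replicates can be regenerated in isolation and
scenario runs are order-independent.

Because the unstratified Cox model is misspecified under frailty (the
marginal hazards are not proportional), its target is defined
operationally: the coefficient recovered from a very large uncensored
cohort (`marginal_hr_parameter()`).  The default evaluation size is
200,000 pairs, a desk-scale choice with Monte-Carlo standard error
about 0.003 on the log scale — small against every bias this package
measures; larger sizes are one argument away.  Noncollapsibility places
this value strictly between $\beta$ and 0, and a null conditional
effect forces a null marginal effect, which is returned exactly.

`run_scenario()` reports, per estimator and per target (conditional and
marginal), the mean bias, the empirical SD of the estimates (MCSE), the
mean estimated SE (MESE), $\mathrm{RMSE} = \sqrt{\mathrm{bias}^2 +
\mathrm{MCSE}^2}$ (so the identity holds exactly on the replicate set,
using the $n-1$ SD), Wald coverage and rejection rates, and the
stratified log-rank rejection rate.  Replicates where an estimator
fails — a boundary $G/H$, no events — are excluded for that estimator
and counted in `n_failed`; with 250-pair cohorts under the study's
censoring levels such failures are essentially absent, but the policy
matters for small-`n` exploration.  The packaged study grid
(`replicate_table()`) runs 2000 replicates of $n = 250$ pairs per cell,
the scale at which the reported behaviors (stratified PMLE unbiased for
$\beta$ throughout; unstratified estimates pulled toward the null by
noncollapsibility, further distorted as censoring grows, and biased
from *both* targets under exposure-dependent censoring) are resolved
against Monte-Carlo noise of a few thousandths.

What the generator does **not** emulate: covariate-driven matching
(pairs are exchangeable by construction), non-exponential baselines
(Weibull shapes were out of scope), recorded tied times, staggered
entry or competing risks.  Passing tests therefore demonstrate
correctness of the estimators under the stated frailty model, not
robustness to those real-data features.

## Propensity matching

`fit_propensity()` is a plain maximum-likelihood logistic model;
`caliper_match()` implements greedy nearest-neighbor matching without
replacement, caliper fixed at 20% of the reference-group score SD on
the probability scale (the scale on which such calipers are usually
quoted).  The processing order is a genuine design choice, since the
source recipe specifies none: exposed subjects are matched in
descending propensity order — hardest-to-match first, the common greedy
heuristic — with ties broken by subject id, making the output fully
deterministic.  The order affects which controls are consumed early,
rarely how many pairs form.  Covariate transforms belong to the caller;
the matcher sees only the columns it is given.  Optimal (network-flow)
matching and matching with replacement are out of scope.

## Known limitations

* Breslow ties only; no Efron or exact partial likelihood.
* 1:1 matching only; no 1:m or variable-ratio designs, no more than two
  exposure levels.
* No variance for the MH rate ratio or the conditional-Poisson MLE.
* No time-varying covariates, left truncation or frailty *fitting*; the
  frailty model is a data-generating device here, not an estimator.

## A worked call

```{r example}
counts <- tabulate_pairs(fixture_cohort("rotterdam_counts"))
counts
common_hr_pmle(counts)
stratified_logrank(counts)
pair_c_statistic(counts)
```
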