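# pairhr

Hazard-ratio estimation for 1:1 matched (pair-matched) cohort studies
with censored time-to-event outcomes — for epidemiologists and
biostatisticians analyzing matched cohorts or propensity-matched
observational data.

## What it computes

In a Cox model stratified on matched pairs,
λ<sub>ke</sub>(t) = λ<sub>k0</sub>(t)·exp(β·e), the partial maximum
likelihood estimator of the common hazard ratio exp(β) has a closed
form.  Classify each pair by which member's observed follow-up time is
shorter and whether members had events; only the "comparable" pairs —
those whose shorter-time member experienced the event — contribute.
With

- **G** = number of pairs where the *exposed* member is the shorter-time
  event case,
- **H** = the same count for the *unexposed* member,

the estimator, its variance, the score (stratified log-rank) test, and
a matched-pair concordance statistic are

```
HR = G/H        var{log(G/H)} = 1/G + 1/H
X² = (G − H)²/(G + H)  ~  χ²(1) under HR = 1
C  = max(G, H)/(G + H),   C/(1 − C) = HR (or 1/HR)
```

Around this core the package provides:

- pair-type classification and tabulation (`classify_pairs`,
  `tabulate_pairs`), with documented tie conventions;
- closed-form inference (`common_hr_pmle`, `stratified_logrank`,
  `pair_c_statistic`, plus a McNemar convenience alias);
- a from-scratch Breslow partial-likelihood Cox engine with strata,
  case weights and pair-clustered sandwich variance (`fit_cox`,
  `score_test_null`) — the unstratified marginal-HR comparator;
- person-time comparators: Mantel–Haenszel rate ratio and the
  conditional-Poisson MLE (`mh_rate_ratio`, `poisson_cmle`);
- an exponential–normal frailty simulator with independent and
  exposure-dependent censoring, the marginal-HR target parameter, and a
  Monte-Carlo study harness (`draw_cohort`, `marginal_hr_parameter`,
  `run_scenario`, `replicate_table`);
- propensity-score estimation and caliper pair-matching without
  replacement (`fit_propensity`, `caliper_match`, `ps_match_cohort`);
- long/pair CSV input-output and a thin command-line wrapper
  (`inst/cli/pairhr`).

The closed form matters because it is *less sensitive to censoring*
than the unstratified ("marginal") estimator: the simulation machinery
in this package demonstrates that the stratified PMLE stays centered on
the conditional HR even when censoring rates differ fourfold between
arms, while unstratified estimates are pulled away from both the
conditional and the marginal target.

## Worked example

A packaged synthetic cohort reproduces the comparable-pair counts of a
published propensity-matched breast-cancer cohort (446 pairs, exposure
= absence of chemotherapy, outcome = relapse-free survival):

```r
library(pairhr)
counts <- tabulate_pairs(fixture_cohort("rotterdam_counts"))
counts
#> Matched-pair type counts (446 pairs)
#>  n1  n2  n3  n4  n5  n6  n7  n8  n9
#> 100  60  98  75  30  30  28  25   0
#> G = 198  H = 135  (comparable pairs: shorter-time member had the event)

common_hr_pmle(counts)
#> Stratified PMLE (G/H)
#>   HR = 1.4667  (log HR = 0.3830, SE = 0.1116)
#>   95% CI: 1.1785 to 1.8253

stratified_logrank(counts)
#> Stratified log-rank (matched pairs)
#>   chi-squared = 11.9189, df = 1, p = 0.0005557

pair_c_statistic(counts)
#> Matched-pair C-statistic: 0.5946 (odds 1.4667)
#>   favored arm: exposed
```

Read: the exposed arm fails first in 59.5% of comparable pairs; the
odds of that proportion, 1.47, *is* the common hazard ratio, with 95%
CI 1.18–1.83 — an elevated hazard without chemotherapy.

A small Monte-Carlo cell (exposure-dependent censoring, rate ratio 4,
conditional log HR = log 2 ≈ 0.693, marginal target 0.437):

```r
cfg <- scenario_config(250, beta = log(2), censoring = "conditional",
                       censoring_alpha = log(4))
run_scenario(cfg, n_reps = 200, master_seed = 42, marginal_truth = 0.437)
#> Simulation: 250 pairs, beta = 0.693, censoring = conditional, 200 replicates
#> targets: conditional 0.693, marginal 0.437
#>                 estimator      target    bias  mcse  mese  rmse coverage ...
#> 1         stratified_pmle conditional  0.0254 0.240 0.223 0.242    0.945
#> 3        unstratified_cox conditional -0.3856 0.144 0.148 0.411    0.255
#> 4        unstratified_cox    marginal -0.1294 0.144 0.148 0.193    0.870
```

The stratified closed form is unbiased for the conditional HR with
nominal coverage; the unstratified fit is biased from *both* targets
under this censoring pattern.

## Command line

```sh
cli=$(Rscript -e 'cat(system.file("cli", "pairhr", package = "pairhr"))')
Rscript "$cli" simulate --n 250 --beta 0.693 --censoring independent:1 \
        --seed 42 --out cohort.csv
Rscript "$cli" estimate --input cohort.csv --method pmle
Rscript "$cli" classify --input cohort.csv
```
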