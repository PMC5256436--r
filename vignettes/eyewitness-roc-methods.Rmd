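---
title: "Models and methods: signal-detection simulation of identification procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: signal-detection simulation of identification procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineuproc)
```

## The evidence model

Every simulation in lineuproc lives in a one-dimensional Gaussian
signal-detection world. A face viewed at test evokes a *memory strength*:
fillers and innocent suspects draw from the standard normal `N(0, 1)`, the
guilty suspect from `N(d', sigma_guilty)`. `d'` is the true discriminability
of guilty from innocent faces; `sigma_guilty = 1` gives the equal-variance
model and values such as 1.2 the unequal-variance one. These two numbers are
the *only* memory parameters; everything else that differs between
identification procedures is decision process, not memory. That separation is
the point of the package: procedures that share a trial pool share memory
evidence exactly, so any difference between their ROCs is attributable to the
decision rule alone.

Strengths within a lineup are sampled independently. Real lineups induce
correlations (fillers are chosen to resemble the suspect) and real witness
populations mix different `d'` and criterion values; neither is modelled
here, so passing tests support conclusions about the decision rules under
these idealised conditions, not about any empirical data set.

## Trials, criteria and confidence

A target-present (TP) trial of size `N` holds one guilty draw at a uniformly
random position plus `N - 1` filler draws; a target-absent (TA) trial holds
`N` filler draws. The random position doubles as the presentation order for
sequential procedures, so no second shuffle is needed and all procedures can
consume the same pool.

Identification requires the decision variable to *strictly exceed* a
criterion; a strength exactly at a criterion does not produce an
identification. The event has probability zero for continuous draws — the
rule exists so unit tests are deterministic at the boundary.

Confidence is the 1-based index of the inter-criterion interval a strength
falls into: on the fixed seven-criterion scale
`{0.18, 0.23, 0.27, 0.39, 0.67, 1.15, 1.53}` a strength of 1.0 lies between
the fifth and sixth criteria and is level 6, anything above 1.53 is level 8,
and anything at or below 0.18 is level 1, meaning *no identification*. We
chose the interval-index convention (rather than counting criteria exceeded)
because it matches the worked example conventionally used with this scale;
the two labellings differ only by one everywhere above the lowest criterion.
Cumulative response rates at confidence levels above `j` equal the rates at
criterion `c_j`, so the same rate-table functions serve both the fixed scale
and a swept criterion.

Criterion sweeps default to 161 evenly spaced values on
`[-3, d' + 3 max(1, sigma_guilty)]`. The grid is a plotting/integration
resolution, not a model parameter: it spans both distributions to ±3 SD, and
doubling it moves the trapezoidal pAUC of a smooth curve in the fifth
decimal.

## Decision rules

* **Showup** (`run_showup`): identify iff the single strength exceeds the
  criterion. Closed form: `H = pnorm(d' - c)` (sigma-adjusted), `F = pnorm(-c)`.
* **Simultaneous, absolute rule** (`run_simultaneous`): the strongest
  above-criterion photo is identified. A TP hit requires the guilty photo to
  *win* the lineup and clear the criterion.
* **Relative rules**: the winner must beat the runner-up by at least `delta`
  (default 0.15). We read "next-best photograph" as the second-highest
  strength regardless of whether it clears the criterion; under this reading
  `delta = 0` collapses exactly onto the absolute rule, which we treat as the
  defining sanity property. When the margin is too small, `relative_reject`
  rejects the lineup and `relative_guess` picks uniformly between the two
  strongest. The guess coin is flipped once per trial, so one simulated
  witness behaves consistently across the entire criterion sweep.
* **Sequential** (`run_sequential`): photos are judged one at a time in
  presentation order. Under `first_id` the first above-criterion photo ends
  the procedure (a single lap); under `any_id` every above-criterion photo is
  flagged and the strongest flagged photo is the final choice, which makes
  the procedure operationally identical to the absolute simultaneous rule —
  a property the tests verify trial by trial rather than assume.
* **2AFC** (`run_2afc`): the witness prefers whichever of a target–lure pair
  is stronger, with preference strength the difference
  `target - lure ~ N(d', sqrt(1 + sigma_guilty^2))`. The rating ROC sweeps a
  criterion on that difference, with the mirrored presentation supplying the
  false-alarm axis; the hit rate at criterion zero is the classic proportion
  correct `pnorm(d' / sqrt(1 + sigma_guilty^2))`, and the full area under the
  analytic curve is `pnorm(2 d' / sqrt(2 (1 + sigma_guilty^2)))`.

In a fair TA lineup every filler is exchangeable, so the innocent-*suspect*
false-ID rate is the TA identification rate divided by `N` (the
`divide_by_n` convention, the default, applied uniformly at every criterion
and confidence level). The alternative `designated_innocent` convention
scores position 1 of each TA trial as the innocent suspect; the two agree in
expectation and the divide-by-N version has strictly smaller Monte Carlo
variance, which is why it is the default.

The `first_id` sequential rule is the one procedure whose hit rate is *not*
monotone in the criterion: past a point, liberal criteria let an early filler
end a TP trial before the guilty photo is reached, and in the limit the hit
rate equals the chance that the guilty photo comes first, `1/N`. Its ROC
therefore folds back on itself.

## ROC measurement

`roc_points()` orders operating points from conservative to liberal.
`pauc()` integrates trapezoidally from `F = 0` to `f_max`, interpolating at
`f_max`, and reports the *raw* area (a chance curve gives `f_max^2 / 2`), so
areas can be compared against reference squares of 0.01 and 0.001 drawn on
the unit square. Two boundary policies matter:

* a curve that terminates before `f_max` (lineup curves end near `F = 1/N`)
  is extended horizontally at its last hit rate — the conservative completion
  consistent with "no further hits are gained by relaxing nothing";
* a folded (`first_id`) curve is reduced to its upper envelope in `F`, with a
  warning, because the area under a self-intersecting path is ill-defined;
  no headline quantity in the package depends on a folded curve's pAUC.

`bootstrap_pauc()` resamples TP and TA trials with replacement,
independently, 2000 times by default, rebuilding the entire swept ROC per
replicate, and reports the percentile interval (2.5/97.5 at the default 95%
level). Resampling trials rather than confidence bins keeps the replicate
ROCs realisable data sets. Point statistics (`bias_stats`) clamp rates to
`[1/(2n), 1 - 1/(2n)]` before the normal-quantile transform so empirical 0
and 1 rates stay finite, and the diagnosticity ratio `H/F` is returned as
`NA` (with a warning) at `F = 0` instead of infinity.

The analytic family `analytic_roc_from_auc()` —
`H = pnorm(sqrt(2) qnorm(AUC) + qnorm(F))` — generates equal-variance ROCs of
known accuracy; `diagnosticity_bias_curves()` traces the diagnosticity ratio
and the bias statistic `c = -0.5 (z(H) + z(F))` along them, exhibiting the
central measurement point: at fixed true accuracy the diagnosticity ratio
varies freely with bias (a line `H = D F` holds `D` constant while `c`
varies), so `D` cannot separate the two.

## Bayesian measures

`posterior_guilt()` is Bayes' rule on an identification outcome, with filler
identifications and rejections pooled as the non-identification event (the
convention of the information-gain literature). `information_gain_curve()`
places the criterion `k` SD units above the guilty-suspect mean
(`c = d' + k`), implying `H = pnorm(-k / sigma_guilty)` and
`F = pnorm(-(d' + k))`, and traces posterior and gain across the
target-present base rate. The exact `(d', k)` pairs behind published
illustrations of these curves are not standardised, so the defaults
`k ∈ {0, 1}` are configuration, and the package's claims about the curves
are the qualitative ones the tests verify: gains pin to zero at base rates 0
and 1, higher `d'` yields higher identification gain at equal bias, and a
conservative low-`d'` witness can out-gain a liberal high-`d'` one — the
confound the curves are meant to demonstrate.

## Experiment bundles and problem sizes

`replicate_figure()` runs the six canonical studies (five-task ROC
comparison, pAUC-with-CI grid, diagnosticity curves, information-gain
curves, decision-rule comparison, sequential-vs-simultaneous comparison)
under a single seed with a full configuration echo; CSV tables are the
canonical output, plots are conveniences. Defaults are 10,000 trials per
trial type per condition and 2000 bootstrap replicates — the sizes at which
the package's headline numbers are quoted. The test suite exercises the same
code at 400–10,000 trials and 50–400 replicates, sizes chosen so the full
suite runs in seconds while keeping Monte Carlo tolerances (4 binomial SEs)
meaningful.

## Known limitations

Independence of within-lineup strengths, homogeneous witnesses, a fixed
criterion across sequence positions, and a single lap (for `first_id`) are
modelling assumptions, not empirical claims; relaxing any of them changes
the sequential ROCs in particular. pAUC values from step-function empirical
ROCs carry a small downward trapezoid bias relative to the smooth theoretical
curve; comparisons in this package always contrast pAUCs computed the same
way, so the bias cancels to first order.
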