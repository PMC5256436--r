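# lineuproc

Signal-detection simulation and ROC analysis of eyewitness identification
procedures.

Researchers who compare identification procedures — showups, simultaneous and
sequential lineups — need a measure of witnesses' ability to discriminate
guilty from innocent suspects that is not contaminated by their willingness
to identify *someone*. Single-point statistics such as the diagnosticity
ratio `D = H/F` confound the two: every point on the line `H = D·F` has the
same diagnosticity but a different response bias. The ROC, and its partial
area up to a maximum false-alarm rate (pAUC), separates them. `lineuproc`
provides the simulation and measurement machinery to study this claim and
the decision rules behind it.

## The model

Memory strengths are Gaussian: fillers and innocent suspects draw from
`N(0, 1)`, the guilty suspect from `N(d′, σ)` (σ = 1 equal variance, 1.2
unequal). A target-present lineup of size `N` is one guilty draw plus
`N − 1` filler draws; a target-absent lineup is `N` filler draws. An
identification occurs when a decision variable exceeds a criterion `c`:

* **showup** — the single strength; `H = Φ(d′ − c)`, `F = Φ(−c)`;
* **simultaneous lineup** — the lineup maximum, under an absolute rule
  (strongest above-criterion photo) or relative rules requiring a winning
  margin Δ, with ties resolved by rejection or guessing;
* **sequential lineup** — photos one at a time: stop at the first
  above-criterion photo (single lap), or flag all and keep the strongest;
* **2AFC** — the target–lure strength difference, `N(d′, √(1 + σ²))`.

Fair target-absent lineups spread false identifications over `N`
exchangeable fillers, so the innocent-suspect false-ID rate is the TA
identification rate divided by `N`. Sweeping `c` over a shared trial pool
traces each procedure's ROC on identical evidence, so curve differences are
pure decision process. Measurement tools include trapezoidal pAUC with
percentile-bootstrap CIs, the bias statistic `c = −0.5(zH + zF)`,
diagnosticity-versus-bias curves at fixed AUC, and Bayesian
posterior-of-guilt / information-gain curves over the target-present base
rate.

## Worked example

```r
library(lineuproc)

model <- evidence_model(1.5)                       # d' = 1.5, equal variance
pool  <- sample_trials(model, n_tp = 10000, n_ta = 10000,
                       lineup_size = 6, seed = 123)

rates <- run_simultaneous(pool)                    # absolute rule, TA / 6
pauc(roc_points(rates), f_max = 0.16)
#> [1] 0.07551587

bootstrap_pauc(pool, "simultaneous", f_max = 0.16, n_boot = 500, seed = 124)
#> <pauc_boot> simultaneous: pAUC = 0.07552 over F in [0, 0.16],
#>   95% CI [0.07413, 0.07693] (500 boot, 10000 TP / 10000 TA)

bias_stats(H = 0.63, F = 0.03)
#> # A tibble: 1 × 5
#>       H     F d_prime_est     c     D
#>   <dbl> <dbl>       <dbl> <dbl> <dbl>
#> 1  0.63  0.03        2.21 0.774    21

posterior_guilt(0.5, H = 0.63, F = 0.03, response = "id")
#> [1] 0.9545455
```

The pAUC of 0.0755 over `F ∈ [0, 0.16]` is the six-person lineup's
bias-free accuracy summary at `d′ = 1.5` (a chance ROC would give
`0.16²/2 = 0.0128`). The single operating point `(H, F) = (0.63, 0.03)`
illustrates the confound: its diagnosticity ratio of 21 reflects the
conservative bias (`c = 0.77`) as much as the accuracy (`d′ ≈ 2.2`); and a
witness at that point converts a 50% prior of guilt into a 95% posterior.

`replicate_figure()` bundles the six canonical studies (five-task ROC
comparison, pAUC ± CI grid, diagnosticity curves, information-gain curves,
decision-rule comparison, sequential-vs-simultaneous comparison) under one
seed with CSV output and a JSON config echo; `plot_roc()`,
`plot_diagnosticity()` and `plot_information_gain()` draw them.

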