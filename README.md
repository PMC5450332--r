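# survrules

Interpretable survival modelling for right-censored data: **survrules**
induces a compact set of conjunctive rules, each concluding with a
Kaplan-Meier survival curve, using a separate-and-conquer covering
algorithm whose rule-quality measure is the two-sample log-rank statistic.
It is aimed at biostatisticians and clinical researchers who want
patient subgroups with distinct survival profiles stated as readable
conditions (`pnodes >= 4.5 AND progrec < 28.5`) rather than as coefficients
or tree paths.

## The method in brief

A rule is `IF c1 AND ... AND ck THEN S(t | premise)`: the premise is a
conjunction of attribute tests (equality for nominal attributes, thresholds
`A < a` / `A >= a` merged post hoc into intervals `A in [x, y)` for numeric
ones), and the conclusion is the Kaplan-Meier estimate fitted on the covered
training records. Rules are learned one at a time; each must cover at least
`mincov` (default 7) previously uncovered records, and induction stops when
the training set is fully covered.

Candidate conditions are scored by the log-rank statistic `x²/y` between
covered and uncovered records over the distinct event times `t`:

    x = Σ_t ( d_u^t − r_u^t / (r_c^t + r_u^t) · (d_c^t + d_u^t) )
    y = Σ_t  r_c^t r_u^t (d_c^t + d_u^t)(r_c^t + r_u^t − d_c^t − d_u^t)
             / ( (r_c^t + r_u^t)² (r_c^t + r_u^t − 1) )

with `d`/`r` the weighted event and at-risk counts per group. Growing adds
the best admissible condition exhaustively; pruning removes conditions while
the statistic strictly improves. Prediction averages the curves of all
covering rules and falls back to the whole-sample default curve. Evaluation
uses the censoring-weighted Brier score and its time integral (IBS) with
inverse-probability-of-censoring weights from the flipped-status
Kaplan-Meier estimate, under repeated censoring-stratified
cross-validation. Rule significance is assessed by per-rule log-rank tests
with Benjamini-Hochberg false-discovery-rate control.

Details, assumptions and numerical choices are laid out in the vignette
`vignettes/survival-rule-induction.Rmd`.

## A worked example

```r
library(survrules)
library(survival)

sim <- generate_survival_data(
  n = 300,
  attributes = c(list(risk = attr_nominal(c("low", "high"))),
                 setNames(replicate(10, attr_numeric(0, 1), simplify = FALSE),
                          paste0("x", 1:10))),
  regions = list(region_spec(list(condition("risk", "=", "high")), rate = 1)),
  baseline_rate = 0.04, censoring_fraction = 0.3, seed = 11)

fit <- survrules(Surv(time, status) ~ ., data = sim$data)
summary(fit)
#> Survival rule set on 300 records (mincov = 7 )
#>   rules:                 12
#>   mean rule length:      9.42
#>   mean coverage:         19.7%
#>   significant rules:     100.0% (BH-adjusted p < 0.05)

format_rule(fit$rules[[1]])   # leading conditions of the first rule
#> [1] "risk = low AND x6 in [0.0084587231976911426, 0.95666856877505779) AND ..."

cv <- cross_validate(Surv(time, status) ~ ., data = sim$data,
                     mincov = 7, k = 10, repeats = 1, seed = 11)
cv
#> 1 x 10-fold censoring-stratified cross-validation (mincov = 7)
#>   mean IBS (rules):      0.1203
#>   mean IBS (KM default): 0.1873
#>   mean rules per fold:   12.9
```

The summary says the learner found 12 subgroups, all with significantly
distinct survival after FDR adjustment; the cross-validated integrated
Brier score (lower is better) improves markedly on the no-covariate
Kaplan-Meier baseline because the data contain a genuine 25-fold hazard
contrast on the planted `risk` attribute, which the leading rules test.

A command-line interface wrapping the same functions is installed at
`inst/cli/survrules` (subcommands `train`, `predict`, `evaluate`,
`simulate`; see `?cli_main`).

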