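# slabspline

Dose–response regression for semicontinuous exposures — variables with a
point mass at exactly zero (nonusers) and a continuous distribution over
positive doses (users) — without the **safe-dose assumption**.

## The problem

Pharmacoepidemiologic analyses routinely model the dose–response function

&Delta;(x) = E[Y | X = x] − E[Y | X = 0],

the expected outcome difference between receiving dose *x* and receiving
none. Any model of the form E[Y | X = x] = &beta;&#8320; + f(x) with
f(x) &rarr; 0 as x &rarr; 0⁺ — a linear term, or a conventional spline —
silently assumes &Delta;(x) &rarr; 0 for small doses, and its pointwise
variance collapses with it (for the linear model,
Var(&Delta;&#770;(x)) = x²·Var(&beta;&#770;&#8321;)). The result is an
apparently precise "safe" low-dose range that may be an artifact of the
model, not the data.

`slabspline` implements two remedies and the machinery to evaluate them:

* **Spike-at-zero**: add the indicator 1(x &gt; 0), giving exposed
  subjects their own intercept. Then &Delta;(x) = &beta;&#8321; +
  &beta;&#8322;x (linear case) and
  Var(&Delta;&#770;(x)) &rarr; Var(&beta;&#770;&#8321;) &gt; 0 as
  x &rarr; 0 — the confidence band no longer pinches at the origin.
  Spline bases are *anchored at zero* (columns shifted to vanish at
  x = 0) so that the spike coefficient is directly the limiting effect of
  an infinitesimally small dose.
* **Slab-and-spline**: when positive low doses are sparse, a natural
  cubic spline is constrained to have zero slope at (and left of) its
  lower boundary knot, so the exposed-group curve is a constant "slab"
  below the first knot that joins the spline with a continuous first
  derivative. This spends one parameter fewer than spike + unconstrained
  spline. The constrained basis is built by multiplying the natural
  spline basis by an orthonormal null-space transform of its
  derivative-at-the-first-knot row vector.

Around these sit a catalog of nine modeling strategies (linear,
quadratic, categorical, natural cubic splines with several knot choices,
the slab, and a zero-exclusion comparator), OLS fitting with Huber–White
(HC0/HC1) and cluster-robust sandwich standard errors, delta-method
pointwise confidence bands for &Delta;&#770;(x), and a Monte-Carlo engine
reporting bias, empirical vs. model-based standard errors, and coverage.

## Worked example

Simulate one study (dose 0 with probability 0.25, otherwise
2·Beta(1, 5); outcome Y = 10 + 0.5·1(X&gt;0) − 2.4X + 4.8X² + N(0, 1.5²)),
fit the spiked natural cubic spline, and read off the dose–response curve:

```r
library(slabspline)
set.seed(2026)
cfg <- scenario_config(dose_scenario = 1, spike = TRUE)
dat <- simulate_sample(cfg, n = 1000)

fit <- fit_model(catalog_models()[["strategy6"]], dat$dose, dat$outcome)
fit
#> dose-response fit, strategy 6 (ncs(1/8,1/2,7/8) + spike), n = 1000
#>               estimate  robust_se
#> (Intercept) 10.0848695 0.09429976
#> spike        0.2226799 0.14134519
#> ns1          1.0304576 0.20137605
#> ns2          1.9946644 0.16460406

delta_curve(fit, c(0.01, 0.05, 0.25, 0.5, 1, 1.5))
#>   dose estimate    se ci_lower ci_upper reference_dose
#> 1 0.01   0.2166 0.139  -0.0556    0.489              0
#> 2 0.05   0.1922 0.130  -0.0619    0.446              0
#> 3 0.25   0.0849 0.111  -0.1330    0.303              0
#> 4 0.50   0.3095 0.128   0.0583    0.561              0
#> 5 1.00   2.7449 0.222   2.3092    3.181              0
#> 6 1.50   5.5718 0.469   4.6517    6.492              0
```

The `estimate` column is &Delta;&#770;(x) relative to dose 0 (true values
0.48, 0.39, 0.20, 0.50, 2.90, 7.70 here); `se` is the delta-method
standard error from the HC1 sandwich covariance. Note the low-dose SEs
(&approx;0.13–0.14) are bounded below by the spike SE rather than
shrinking to zero: the model does not manufacture certainty at doses it
barely observes.

A Monte-Carlo comparison of strategies (here 30 replicates for
illustration; the bundled configs use 500):

```r
mt <- run_scenario(cfg, catalog_models()[c(1, 3, 6, 8)],
                   grid = c(0.05, 0.5, 1), M = 30, seed = 1)
mt[, c("model_label", "dose", "truth", "mean_estimate",
       "empirical_se", "average_se", "coverage")]
```

## Command line

A thin front end over the same functions:

```sh
inst/cli/slabspline simulate --config inst/extdata/configs/scenario1_spike.yaml \
    --out-dir out --seed 11
inst/cli/slabspline fit --data claims.csv --strategy 8 --cluster-col patient \
    --covariates age,parity --knot-scale 300 --out-dir out
inst/cli/slabspline basis --kind slab --knots 0.4375,0.625,0.8125 \
    --range 0,1,101 --out slab_basis.csv
```

Outputs are full-precision CSVs with a JSON manifest; identical seeds
reproduce identical bytes.

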