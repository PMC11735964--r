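---
title: "Modeling dose-response at low doses: spikes, slabs, and splines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dose-response at low doses: spikes, slabs, and splines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabspline)
```

## The estimand and the safe-dose assumption

Let $X \ge 0$ be a semicontinuous dose (positive probability of exactly
zero, continuous above zero) and $Y$ a continuous outcome. The estimand
throughout is the dose-response contrast
$$\Delta(x) = \mathrm{E}[Y \mid X = x] - \mathrm{E}[Y \mid X = 0],$$
estimated as a linear contrast $c^\top\hat\beta$ of regression
coefficients, with delta-method variance $c^\top \hat V c$ where $\hat V$
is a heteroskedasticity-consistent (sandwich) covariance.

Any mean model $\beta_0 + f_\beta(x)$ whose exposure terms vanish as
$x \to 0^+$ implies $\Delta(x) \to 0$ *by construction* — the safe-dose
assumption — and its estimated variance collapses with it: for the simple
linear model, $\mathrm{Var}(\hat\Delta(x)) = x^2\,
\mathrm{Var}(\hat\beta_1)$. When no safe dose truly exists, such models
are simultaneously biased at low doses and overconfident about that bias.

Adding a spike-at-zero indicator $1(x > 0)$ removes the assumption:
$\Delta(x) = \beta_1 + (\text{exposure terms})$ and
$\lim_{x\to 0}\mathrm{Var}(\hat\Delta(x)) = \mathrm{Var}(\hat\beta_1)
\ge 0$. The spike coefficient is interpretable as the total effect of an
infinitesimally small dose — including any behavioral (nocebo/placebo)
component of being exposed at all.

## Basis construction

**Natural cubic splines.** `ncs_basis()` evaluates a natural cubic
spline (piecewise cubic, linear outside the boundary knots, continuous
second derivatives) through `splines::ns()`, with the first and last of
the supplied knots used as boundary knots; $K$ knots give $K-1$
non-intercept columns. No specific basis formula is mandated: the
package's contract (enforced by the test suite against an independent
truncated-power construction) is span equivalence, since any basis
spanning the same function space yields identical fits and contrasts.

**Anchoring at zero.** When a spike is included, every exposure column
has its value at $x = 0$ subtracted (`anchor_at_zero = TRUE`). This is an
affine reparametrization — fitted values and $\hat\Delta(x)$ are
unchanged to machine precision — but it makes zero-dose rows
intercept-only, so the intercept is exactly the zero-group outcome mean
and the spike coefficient is exactly the limiting low-dose effect. That
separability is asserted at $10^{-10}$ in the tests.

**The slab-and-spline basis.** `slab_spline_basis()` spans precisely the
subspace of the natural-spline span whose members satisfy $f'(k_1) = 0$
at the lower boundary knot $k_1$. Because the natural spline is linear
left of $k_1$, these functions are constant ("a slab") on $[0, k_1)$ and
join the interior spline with a continuous first derivative. The
construction is convention-independent: evaluate the per-column
derivatives of the unconstrained basis at $k_1$ (a two-point slope on the
linear tail, exact in floating point), and multiply the basis by an
orthonormal null-space transform of that row vector. The result has one
column fewer than the unconstrained basis, and a fit using it equals
equality-constrained least squares with the zero-derivative constraint
(tested at $10^{-8}$ against a KKT oracle).

**Why the catalog's slab model keeps the spike.** A design question with
no single obvious answer is whether the slab *replaces* the zero-dose
indicator (pooling nonusers into the slab) or *accompanies* it. Pooling
would force $\hat\Delta(x) \equiv 0$ with zero standard error below
$k_1$ — re-imposing the safe-dose assumption in exactly the region the
method is meant to protect, and contradicting both the intended
degrees-of-freedom accounting (one fewer than spike + spline) and the
behavior expected of the method at sparse low doses (a flat low-dose
effect estimate with a nonzero interval). Strategy 8 therefore fits
intercept + spike + anchored slab basis: the exposed-group curve is a
constant $\beta_0 + \beta_1$ on $(0, k_1)$, $C^1$ at $k_1$, and
$\hat\Delta(x) = \hat\beta_1$ with
$\mathrm{SE} = \mathrm{SE}(\hat\beta_1)$ throughout the slab region. The
standalone basis remains available for users who do want the pooled
variant.

**Dose categories.** `dose_categories()` reserves a category for exactly
zero and bins positive doses into left-open right-closed intervals
(`(0, b1]`, ..., `>bk`). The categorical model uses the zero-dose
category as reference, since $\Delta(x)$ is defined against dose 0. A
category empty in a given sample is dropped from the design and grid
points falling in it are reported missing rather than extrapolated.

## The nine strategies

`catalog_models()` enumerates: (1) linear; (2) linear + spike;
(3) quadratic + spike; (4) categorical with breaks 1/3, 2/3; (5) natural
spline, knots 1/8, 1/2, 7/8; (6) the same + spike; (7) natural spline,
knots 1/3, 1/2, 2/3, + spike; (8) spike + slab-and-spline, knots 7/16,
5/8, 13/16; (9) natural spline fitted to positive doses only, contrasts
relative to the minimum observed positive dose. Knot and break values are
taken literally as absolute doses — they are plausible interior
placements for both bundled dose scenarios — and `knot_scale` rescales
all of them at once for exposures on other scales (e.g. milligram
equivalents). Strategy 9 estimates a different target (effect relative to
the lowest observed dose, not to nonuse); its curve is expected to track
the spiked spline's shape at moderate doses with a roughly constant
vertical offset, and grid points below the minimum observed dose are
undefined and reported missing.

## Estimation and uncertainty

Fitting is ordinary least squares. Standard errors come from the
Huber-White sandwich estimator via the `sandwich` package, HC1 by
default; the analysis that motivated the package reports Huber-White
standard errors without naming a small-sample variant, and at the default
$N = 1000$ with at most six parameters HC0 and HC1 differ by under one
percent, so the choice is exposed (`hc_type`) but inconsequential at that
scale. With cluster identifiers the meat sums within-cluster scores
(`sandwich::vcovCL`); HC1 then applies the usual
$G/(G-1)\cdot(n-1)/(n-p)$ factor, and HC0 is left unadjusted so that
singleton clusters reproduce the observation-level estimator exactly.

Confidence limits use normal quantiles (1.96 at the default 0.95), the
multiplier the simulation literature this package serves prints on its
interval bars; `level` is configurable. Contrasts difference out
covariate columns, so adjusted models yield conditional dose effects
without reference covariate values.

## The synthetic-data generator

`scenario_config()` encodes the generating mechanism used by the
simulation study: doses are 0 with probability 0.25, otherwise
$\gamma_X \cdot \mathrm{Beta}(\alpha_X, 5)$, with scenario 1
($\alpha_X = 1, \gamma_X = 2$; doses dense near zero) and scenario 2
($\alpha_X = 6, \gamma_X = 1$; doses sparse near zero); outcomes follow
$Y = 10 + \beta_1 1(X>0) - 2.4X + 4.8X^2 + \varepsilon$,
$\varepsilon \sim N(0, 1.5^2)$, with $\beta_1 = 0.5$ (spike present) or
$0$. A Beta draw that underflows to exactly zero (possible only for
$\alpha_X < 1$, probability essentially zero) is redrawn so the exposure
indicator identifies the mixture arm exactly.

What passing tests on these data do and do not show: the generator
produces independent observations, homoskedastic Gaussian errors, a
polynomial truth, and no confounding. Real claims data — which the
`generate_applied_fixture()` table imitates only qualitatively
(zero-inflated right-skewed doses in pill-size multiples, repeated
patient identifiers, covariates) — feature measurement error in filled
vs. consumed dose, confounding by indication, heteroskedasticity, and
semicontinuous outcomes. Calibration demonstrated in simulation therefore
validates the *estimation machinery* (bases, contrasts, sandwich
variances), not robustness to those threats; the fixture is labeled
synthetic and matches no real cohort's moments.

## The Monte-Carlo engine

`run_scenario()` repeats: draw a sample, fit each strategy, evaluate
$\hat\Delta$ and its SE on a dose grid; then aggregates the mean
estimate, bias, empirical SE (SD of estimates across replicates), average
model SE, and coverage of $\pm 1.96\,\mathrm{SE}$ intervals against the
generating truth. Aggregation is streaming (sums and sums of squares;
the one subtraction is benign at these magnitudes), so replicate output
need not be stored. Failures inside a replicate (e.g. a collinear design
in a degenerate draw, or an empty dose category) are caught per strategy,
recorded with a reason, and excluded from that cell's denominator, which
is reported as `n_reps`.

Reproducibility uses per-replicate substreams: the master seed generates
one sub-seed per replicate and each replicate reseeds from its own, so
results are independent of execution order and any single replicate can
be reproduced alone. Strategy 9's truth is computed per replicate against
that replicate's minimum observed positive dose.

The default evaluation grid is $\{0.01, 0.025, 0.05\}$ — probing the
near-origin region where the methods differ most — plus 19 evenly spaced
doses from $0.05\gamma_X$ to $0.95\gamma_X$. The default replicate count
for the bundled configurations is $M = 500$, which resolves a coverage
proportion near 0.95 to a Monte-Carlo SE of about 0.0097 and keeps a full
nine-strategy scenario to desk scale; $M = 5000$ remains a configuration
change away.

**Interpreting simultaneous coverage checks.** A band of $\pm 0.02$
around 0.95 is roughly $\pm 2$ Monte-Carlo SEs for *one* grid point at
$M = 500$. The minimum over the 22-point default grid routinely falls
2-3 MC SEs below the truth even for a perfectly calibrated method, and
because all grid points share replicates, whole-grid excursions move
together. Checks of per-point coverage across an entire grid should
either widen the band to account for the minimum (the suite uses 3.5 MC
SEs per point plus a 3-MC-SE bound on the grid average) or increase $M$;
the suite also retains the stricter single-point band verbatim to
document this behavior, and that check is expected to fail for most
seeds at $M = 500$.

## Numerical choices

* Knot validity requires at least three strictly increasing, strictly
  positive knots; two-knot spline requests are errors, not silently
  degraded fits.
* $C^1$ verification of the slab join uses central differences with step
  $10^{-5}$ and tolerance $10^{-6}$ — far above double-precision noise,
  far below any practically meaningful kink.
* The null-space transform is computed once per knot set from a full QR
  of the derivative row's transpose; it is deterministic, so bases built
  at fit time and at prediction time coincide exactly.
* Rank checks use pivoted QR and name the offending columns; fits with
  $n \le p$ are refused.
* Near-zero limit checks compare at $x = 10^{-9}$, where
  $\mathrm{SE}(\hat\Delta)$ differs from $\mathrm{SE}(\hat\beta_1)$ by a
  covariance term of relative order $10^{-10}$; tolerances sit at
  $10^{-6}$, above that term and decisively below any safe-dose collapse.
* CSV output formats doubles with 17 significant digits so files
  round-trip bit-exactly; character fields are quoted (model labels
  contain commas).

## Limitations

Only continuous outcomes and identity links are supported; binary,
count, and time-to-event extensions would change both the estimand and
the variance machinery. The spike and slab devices address the modeling
of low-dose effects, not confounding by indication — users systematically
differ from nonusers in ways no zero-dose indicator repairs. Knot and
slab-boundary placement must be prespecified from the dose distribution;
a slab is advisable only where positive low doses are genuinely sparse,
since it flattens real curvature below the first knot. Multiple
imputation and weighting, used in applied analyses of this design, are
out of scope.
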