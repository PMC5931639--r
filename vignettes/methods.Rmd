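---
title: "Estimating city-level travel patterns from street-imagery counts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating city-level travel patterns from street-imagery counts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetcount)
```

## The problem

Routine surveillance of urban travel is thin: censuses record only the
usual commute mode once a decade, and telephone surveys of walking and
cycling are weakly powered at the city level. Archived street imagery offers
a complementary signal — every panorama is a time-stamped observation of who
was on the street. `streetcount` implements a full pipeline for turning
manual road-user counts in sampled street images into city-level predictions
of commute mode shares and past-month walking/cycling participation, and for
quantifying how well those predictions cross-validate.

The pipeline has five stages, each exposed as ordinary functions:

1. **Location sampling** — one random point per street-network link, a
   simple random subsample of 2000 points per city, and selection of 1000
   locations with archived panoramas by a year-priority rule.
2. **Annotation** — two images per location at opposite headings (0° and
   180°; four headings double-count road users whose position overlaps
   adjacent fields of view), each labelled with ordinal count bins
   (0, 1–3, 4–6, >6) for seven road-user categories.
3. **Aggregation** — bins collapse to per-city *presence counts* (images
   with at least one observation of a mode), plus monthly image
   proportions, season shares and bootstrap SDs of the counts.
4. **Modelling** — beta regression for proportion outcomes, Huber robust
   regression for right-skewed continuous cycling outcomes, OLS for walking
   outcomes; leave-one-out cross-validation (LOOCV) with PRESS-guided
   backward elimination selects predictors.
5. **Gender split** — cyclist gender counts pooled over four
   observation-balanced groups of cities, compared with survey gender
   ratios.

Because the imagery itself is proprietary, the package ships a seeded
synthetic-city generator with known ground truth; every stage is tested
against it, and the same code runs unchanged on a deposited per-city CSV.

## Models

### Beta regression

Mode shares and participation prevalences live in (0, 1), so the main
family is the beta distribution in its mean–precision parameterisation,

$$f(y;\mu,\phi)=\frac{\Gamma(\phi)}{\Gamma(\mu\phi)\,\Gamma((1-\mu)\phi)}
  \, y^{\mu\phi-1}(1-y)^{(1-\mu)\phi-1},\qquad
  \operatorname{logit}(\mu_i)=x_i^\top\beta ,$$

with a single constant precision $\phi>0$ (no dispersion covariates).
`fit_beta()` maximises the exact log-likelihood over $(\beta,\log\phi)$ by
BFGS with an analytic gradient. Starting values are OLS on
$\operatorname{logit}(y)$ for $\beta$ and a method-of-moments value for
$\phi$; convergence requires a small gradient norm and is reported honestly
in the `converged` flag. Wald covariance comes from the numerical Hessian at
the optimum. Outcomes stored in percent are divided by 100 before fitting
(`percent = TRUE` in the model spec); boundary observations must be squeezed
explicitly with `boundary_squeeze()` — none occur in realistic city tables,
so the squeeze is never applied silently.

Model diagnostics use the standardised weighted residual on the logit scale,

$$r_t=\frac{y^*_t-\mu^*_t}{\sqrt{v_t\,(1-h_{tt})}},\qquad
  y^*=\operatorname{logit}(y),\;
  \mu^*=\psi(\mu\phi)-\psi((1-\mu)\phi),\;
  v=\psi'(\mu\phi)+\psi'((1-\mu)\phi),$$

with $\psi$ the digamma function and $h_{tt}$ the leverage from the
weighted hat matrix (weights $\phi\,v\,[\mu(1-\mu)]^2$). These are the exact
mean and variance of $\operatorname{logit}(Y)$ under the fitted beta law,
which the test suite verifies by Monte Carlo. For held-out (LOOCV)
predictions the leverage term is dropped, since the test city is not part of
the training hat matrix; the mean and median of $|r_t|$ are reported as
MSR/MDSR.

### Robust linear and OLS

Days-per-week of cycling are heavily right-skewed by a few high-cycling
cities, so that outcome uses a Huber M-estimator fitted by iteratively
reweighted least squares: weights $w_i=\min(1, k s/|r_i|)$ with tuning
constant $k = 1.345$ (95% efficiency at the Gaussian), and scale $s$
re-estimated each iteration as $1.4826 \times \operatorname{median}|r|$.
Iteration stops when no coefficient moves by more than $10^{-8}$. Walking
outcomes, which are not outlier-dominated, use OLS via QR. Both report
Wald-type covariances (Huber's sandwich form for the M-estimator).

### Cross-validation and variable selection

`loocv()` refits the *fixed* specification $n$ times, predicting each city
from the other $n-1$, and reports PRESS ($\sum(\text{obs}-\text{pred})^2$),
MAE and MDAE on the response scale. Selection is not nested inside the
folds: the procedure mirrors the study design in which PRESS is the
selection criterion itself.

`build_maximal_spec()` screens predictors by Pearson correlation: mode
features with $|r|\ge r_{\min}$ against the outcome, plus month variables
with $|r|\ge r_{\min}$ against any mode feature ($r_{\min}=0.1$; "near-zero"
is not quantified in the source literature, so this is the package's
choice). `sequential_elimination()` then repeatedly tries removing the least
significant predictor (largest Wald $p$ above $\alpha=0.05$, again the
package's formalisation of "low statistical significance"); a removal is
accepted only if it strictly lowers LOOCV PRESS, and the search stops when
no candidate removal lowers PRESS. Numerically tied $p$-values are resolved
in favour of the larger PRESS reduction.

A caveat worth stating plainly: leave-one-out CV is asymptotically
equivalent to AIC, so even for a pure-noise predictor the probability that
removal lowers PRESS is only about $1-\Pr(\chi^2_1>2)\approx 0.84$, and a
further ~5% of the time the noise predictor is Wald-significant at
$\alpha=0.05$ by chance. Monte-Carlo under the package's own generator puts
the end-to-end probability of discarding one planted noise variable at
roughly 0.80–0.88 depending on design. Users should treat the selected set
as a prediction-oriented choice, not as an inference that excluded
variables are irrelevant.

### The ten final models

`final_model_specs()` encodes the published final specifications: beta
regressions for the four commute-share outcomes (walk+public transport,
cycle, motorcycle, car) and four prevalence outcomes, a robust linear model
for days of utility cycling, and OLS for days of utility walking. The
cycle-share model uses $\sqrt{\text{GSV Cycle}}$ — in the original analysis
the untransformed count made the fit pivot on the single extreme
high-cycling city, and the observed-vs-predicted scatter revealed a square
relationship. Month-proportion predictors enter on the percent (0–100)
scale; the source tables are internally ambiguous between the 0–1 and 0–100
conventions across models, and the percent convention is the one this
package adopts throughout (the alternative only rescales those coefficients
by 100).

### Gender split

Cities are sorted by the census male/female commuter-cycling ratio and cut
into $k=4$ contiguous groups. No algorithm for the grouping is stated in
the source; `partition_cities()` formalises it as exhaustive search over the
$\binom{n-1}{3}$ contiguous cut-point triples, minimising the variance of
group observation totals with the within-group ratio range as tie-breaker.
This reproduces the published grouping behaviour (a single dominant city is
isolated, the next two heavy cities pair up) on toy instances checked
against brute-force enumeration. Group ratios pool counts
($\sum M/\sum F$) rather than averaging city ratios; survey comparison
columns are observation-weighted means of city-level survey ratios.

## The synthetic-city generator

`generate_world()` draws, per city: a population; a jittered-grid planar
street network; latent commute shares over {walk, cycle, bus, other public
transport, motorcycle, car} (logit-normal around realistic British-city
levels, normalised to sum to 1); a male cycling share linked to the cycling
level by $\operatorname{logit}(m) = a - b\log(\text{cycle share})$ with
$b = 0.3 > 0$, encoding the observation that gender equality of cycling
rises with cycling levels; a 12-month image mix (Dirichlet concentrated on
March–November with near-zero winter mass, matching how street imagery is
actually captured); and a panorama-year coverage profile.

Key generator choices, all configurable in `generator_config()`:

* **Counts are Poisson.** Per image and mode, counts are drawn Poisson with
  log-rate = base(mode) + city effect + month effect, then binned. The
  source data only ever recorded bins, so no count distribution is
  identifiable from it; Poisson is the simplest model that reproduces the
  observed sparsity (most non-car modes at zero in most images). Rate
  constants are calibrated to the published per-city presence means: car
  presence probability 0.719 (≈1438 of 2000 images), pedestrians ≈209,
  buses ≈27, cyclists ≈18, motorcycles ≈11, parked cycles ≈16.
* **Networks are scaled down.** Full-scale link counts are lognormal with
  mean ≈22,760; the default applies a 1/4 scale factor (floored at the
  stage-two sample size of 2000 so one-point-per-link sampling always
  yields enough candidates) to keep a 34-city world generable in seconds.
* **Year availability** uses two city profiles — 85% "recent-coverage"
  cities rich in 2012/2011 panoramas and 15% "older-coverage" cities rich
  in 2009 — with 2010 panoramas only co-occurring with 2011/2012 ones.
  Under the default priority order (2011 > 2012 > 2010 > 2009 > 2008) this
  reproduces the qualitative selected-year ordering of the original
  harvest: 2012 > 2011 > 2009 > 2008 > 2010.
* **Outcomes**: census shares are logistic-normal perturbations of the
  latent truth (zero noise reproduces it exactly); survey measures are
  fixed monotone maps of the latent walking/cycling levels plus truncated
  Gaussian noise, centred on the published descriptive marginals.
* **Seeding**: one global seed expands into per-city substreams by a stable
  hash of the city identifier, so adding a 35th city cannot perturb the
  first 34 — worlds are reproducible bit-for-bit and extensible.

What the generator does *not* emulate: spatial autocorrelation of road-user
activity within a city, weather, time-of-day structure, annotator error,
and any geographic realism (coordinates are abstract planar). Passing tests
therefore demonstrate that the pipeline recovers planted structure under
idealised sampling — they do not validate the imagery-to-survey link on
real cities, which requires the deposited per-city dataset.

## Numerical choices and degenerate inputs

* Logit linear predictors are clipped to ±30 before exponentiation.
* Zero-length network links, empty networks, rank-deficient designs,
  unknown bin labels, zero commuter denominators and all-zero weights are
  rejected with messages naming the offending field or record.
* A shortfall of eligible locations (fewer than the 1000 target) is a
  warning plus a `shortfall` attribute, not an error — matching how a real
  harvest would proceed with what exists.
* If a published model specification is inestimable on a given table (for
  example a February-proportion column that is identically zero in a small
  world), `fit_final_models()` records the model as non-converged with a
  note instead of failing the whole report.
* Quantiles use the linear-interpolation (type 7) convention; cross-city
  CVs use the sample SD ($n-1$), while bootstrap SDs across replicates use
  the population convention.
* The stabilisation diagnostic declares the running presence proportions
  settled at the first sample size where every mode's running proportion
  varies by less than 0.005 within a trailing 100-image window; the source
  material shows stabilisation curves but states no criterion, so these are
  package defaults chosen to flag ≈1000 images on study-like streams.

## Problem sizes used by the test suite

The shipped tests generate worlds at the full study scale (34 cities ×
2000 images) once and reuse them, plus smaller 6–10-city worlds for
per-module checks; parameter-recovery simulations use n = 500 observations
over 20 seeds, and the bootstrap convergence property uses 50,000
replicates. The complete suite runs in about a minute on one core.

## Limitations

* Constant precision $\phi$: no bias correction and no variable dispersion,
  matching the default behaviour of the estimators used in the original
  analysis.
* The gender analysis needs per-city observation counts, which are not part
  of the deposited table; survey-weighted comparison columns are therefore
  reproducible only qualitatively unless such counts are supplied.
* Selection instability discussed above: PRESS-guided elimination keeps a
  pure-noise predictor in roughly one run in six.
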