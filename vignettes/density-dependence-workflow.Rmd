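---
title: "Detecting density dependence in short annual abundance series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting density dependence in short annual abundance series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densdep)
```

## The question and the data

Annual abundance indices of insect populations — hectares of forest occupied
by overwintering monarch aggregations, transect-count density indices, eggs
per host-plant stem — fluctuate strongly from year to year while sometimes
also declining over decades. Two distinct questions are often conflated: is
the *level* of abundance falling, and does the *growth rate* respond to the
previous year's density? `densdep` addresses the second. Negative density
dependence (a negative effect of last year's density on this year's log
growth rate) indicates regulation — bottom-up resource competition, or
top-down pressure from generalist enemies and disease; a *delayed* (two-year)
feedback would instead point at specialist natural enemies with their own
numerical response. A residual time trend in growth rate, after accounting
for density, signals a declining carrying capacity.

The unit of analysis is the log growth rate of a series of positive annual
indices,

$$R_t = \ln(N_t / N_{t-1}),$$

one observation per gap-free year transition, indexed by its terminal year
$t$. Transitions across missing years are dropped rather than rescaled:
there is no principled way to allocate a multi-year log change to single
years, and the series this workflow targets are short enough that silent
rescaling would distort the variance structure.

## Model family and preparation choices

Candidate models for $R$ are all marginality-respecting subsets of

$$R = \beta_0 + \beta_1 D_{t-1} + \beta_2\,\mathrm{Time}
      + \beta_3 (D_{t-1}\times\mathrm{Time}) + \varepsilon,$$

where $D_{t-1}$ is the previous year's density predictor and
$\varepsilon \sim N(0, \sigma^2_e)$ absorbs both sampling error and
density-independent environmental effects. With $D$ on the raw abundance
scale the feedback is Ricker-type (linear in abundance); ln-transforming $D$
gives Gompertz-type feedback (linear in log abundance), which is the default
for the multi-site density indices where it markedly improves linearity. The
interaction term asks whether the density feedback has changed in strength
over the study period. A separate screening model $R \sim D_{t-1} + D_{t-2}$
tests delayed feedback before the main comparison; it is reported, not merged
into the candidate set, so that the main all-subsets table matches the
direct-feedback family exactly. Exogenous covariates (climate indices and
the like) are deliberately out of scope.

Several preparation details are genuinely open choices; the package fixes
them as follows.

* **Event-year exclusion.** Catastrophic storms kill overwintering adults
  irrespective of density, so growth-rate transitions whose *terminal* count
  is depressed by a documented mass-mortality storm are removed before
  fitting (defaults: terminal years 2002 and 2004; a conservative rerun adds
  2010 and 2016, storms without documented mortality). Exclusion is keyed on
  the terminal year only — a transition that merely *starts* from a
  storm-depressed count is legitimate dynamics and is retained.
* **Standardization.** All predictors (including the time covariate, the
  terminal calendar year) are centred and scaled to mean 0, SD 1 — sample
  (n−1) SD — *after* exclusions and *after* any ln transform, i.e. on the
  dataset actually fitted, so that standardized slopes are comparable across
  analyses. The interaction column is the product of the two standardized
  parents and is not re-standardized; this keeps the design marginality-
  consistent and the interaction interpretable as a per-SD modulation.
* **Site structure.** Multi-site analyses (several regional series sharing a
  dynamic) add a site-level random intercept
  $u_s \sim N(0, \sigma^2_u)$; slopes are pooled. The grouping column is
  taken from the data, so five series over three regions and six series over
  five sites are both expressible without code changes.

## Likelihood machinery

Every model is fitted by maximum likelihood — never REML — because AICc
comparisons across different fixed-effect structures are only valid under
ML. Linear models use the closed form: $\hat\beta$ by QR least squares,
$\hat\sigma^2_e = \mathrm{RSS}/n$, and
$\ell = -\tfrac n2 \ln(2\pi\hat\sigma^2_e) - \tfrac n2$. Random-intercept
models maximize the marginal Gaussian likelihood with covariance
$\sigma^2_u Z Z' + \sigma^2_e I$: for a fixed variance ratio
$\lambda = \sigma^2_u/\sigma^2_e$, $\beta$ and $\sigma^2_e$ profile out in
closed form (block-wise Woodbury identities, no dense matrices), leaving a
one-dimensional profile likelihood in $\ln\lambda$ that is maximized on a
bounded grid ($\ln\lambda \in [-15, 8]$, 47 points) followed by
golden-section refinement, always also evaluating the $\sigma^2_u = 0$
boundary. The optimization is deterministic — fixed grid, no random
restarts — so identical inputs give byte-identical results. Boundary fits
keep both variance parameters in the count $k$ (fixed coefficients +
variance parameters), matching the usual candidate-table df convention. A
dense multivariate-normal log-density (`loglik_dense_oracle()`) is provided
purely as an independent cross-check and is used in the tests, together with
`lme4` fits, to verify the profiled likelihood to $10^{-8}$.

Residual variance is *reported* as the ML estimate, but fixed-effect
standard errors use the degrees-of-freedom-corrected variance
($\mathrm{RSS}/(n-p)$, and $n/(n-p)$-scaled for mixed models). This is the
convention of standard linear- and mixed-model software and reproduces
published Wald intervals for this workflow noticeably better than
pure-ML information SEs, which are systematically too narrow at $n \approx
20$. Degenerate inputs fail loudly: rank-deficient designs, $n \le p$, and
residual variance below $10^{-12}$ (a perfectly collinear response would
otherwise send the likelihood to $+\infty$) are errors, not warnings.

Variance explained is $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ for linear
models and the marginal pseudo-$R^2$
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\sigma^2_u +
\hat\sigma^2_e)$ for mixed models — the share attributable to fixed effects
alone.

## Model selection and averaging

Candidates are ranked by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$; for mixed models $n$ is the
total number of growth observations pooled across sites. Differences
$\Delta_i$ from the best model give Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$, normalized over the *full*
enumerated candidate set. Reports show models with $\Delta < 7$ and flag
$\Delta < 2$ as plausible; ranking ties break toward fewer parameters for
determinism.

Coefficients are averaged *conditionally* (subset averaging): for each term,
weights are renormalized over the models containing it, and the averaged
standard error combines within-model variance and between-model spread,

$$\widehat{\mathrm{SE}} = \sum_i w_i'
  \sqrt{\mathrm{se}_i^2 + (\hat\beta_i - \bar\beta)^2},$$

with each within-model SE first inflated by
$t_{df_i,0.975}/z_{0.975}$ so that the per-model contribution reflects the
small-sample Wald interval. The 95% interval is
$\bar\beta \pm 1.96\,\widehat{\mathrm{SE}}$. Conditional averaging was
chosen over full-model (shrinkage) averaging because the intervals this
workflow is compared against are conditional; the averaged estimate is then
interpretable as "the effect, given that the term belongs in the model",
and the summed raw weight of the containing models (relative importance) is
reported alongside. Exact reproduction of third-decimal published intervals
is not guaranteed — the adjusted-SE variant and the df convention of the
original software are not uniquely determined — but the packaged
overwintering reanalysis agrees with the published intervals to ~0.03.

## The synthetic-data generator

`simulate_series()` runs the data-generating twin of the analysis models:

$$\ln N_t = \ln N_{t-1} + a + b\,D_{t-1} + c\,\tilde t + \mathrm{storm}_t
            + \varepsilon_t,$$

with lognormal process noise ($\varepsilon_t \sim N(0, \sigma_e^2)$ on the
log scale, matching the additive-error structure of the growth-rate models),
storms as additive negative log shocks (exogenous mortality, not a model
term), and, in `simulate_multisite()`, site intercepts drawn once per site.
`monarch_like_scenario()` bundles the three dataset shapes of the motivating
study: a single 24-year Ricker series with negative density dependence
($a = 1.6$, $b = -0.22$, equilibrium ≈ 7 ha), a negative time trend
($c = -0.35$ per standardized year), moderate process noise
($\sigma_e = 0.45$) and storms in 2002/2004 ($-1.2$ log units ≈ 70%
mortality); six 17-year and five 18-year Gompertz site series
($b = -1.4$ and $-1.5$ per ln-unit, $\sigma_e = 0.35$–$0.4$,
$\sigma_u = 0.15$). The multisite slopes were set from stationary-AR
arithmetic so the implied standardized-scale density effects fall in the
−0.5 to −0.7 band reported for these systems; the overwintering equilibrium
and noise echo the hectare scale of the real series.

What the generator does *not* emulate: observation error distinct from
process error (the analysis models conflate them in $\varepsilon$, so the
generator does too), within-year generation structure, spatial coupling
between sites, and heavy-tailed noise. Passing tests therefore show that the
machinery recovers what it assumes — not that real monarch data satisfy
those assumptions.

## Parameter recovery and its honest limits

`parameter_recovery()` simulates replicate multi-site Gompertz datasets
(defaults: 6 sites × 17 years, $b = -0.5$ per ln-unit, $\sigma_e = 0.3$,
$\sigma_u = 0.15$), refits the generating specification on the generator's
own scale (ln-transformed, unstandardized — so the estimand *is* $b$; a
standardized-scale slope would be a different, replicate-varying quantity),
and records the estimate, Wald SE, and 95%-interval coverage. At 500
replicates the mean estimate sits within Monte-Carlo error of $b$ (the
small conditional-ML autoregressive bias is partly offset by the
random-intercept shrinkage). Coverage of the nominal 95% Wald intervals,
however, measures around 86–91%: with a lagged response as predictor, the
finite-sample spread of $\hat b$ exceeds the asymptotic Wald SE by roughly
20% at this series length. This is a property of conditional ML on short
autoregressive panels — `lme4` produces the identical intervals — and users
should read the mixed-model Wald CIs on density slopes as mildly
anti-conservative at these sample sizes. Problem sizes throughout the test
suite (500 × 96-observation refits, scenario analyses at 21–102
observations) were chosen as the smallest designs at which these Monte-Carlo
statements are stable.

## Known limitations

* No REML, random slopes, crossed/nested random effects, residual
  autocorrelation or heteroscedastic error structures — the model family is
  deliberately the small one the candidate table enumerates.
* The packaged overwintering series is compiled from public season reports
  at 2-decimal precision; reanalysis results agree with published values to
  about one unit in the second decimal.
* Missing years cost both the transition into and out of the gap; the
  workflow assumes indices are already effort-corrected densities.
* AICc weights quantify support *within* the enumerated family only; a
  well-supported density term is not evidence against mechanisms (climate,
  habitat loss) that were never candidates.
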