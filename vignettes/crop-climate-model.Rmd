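---
title: "Modelling municipal crop production against climate covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling municipal crop production against climate covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cropclim)
```

## The model

`cropclim` studies how yearly environmental conditions relate to
municipal crop production with a hierarchical Bayesian Poisson model on
the *rate of change* of production. Let $y_{it}$ be the production (in
tons, treated as a count) of one crop in municipality $i$ and year $t$.
The model is

$$y_{it} \sim \mathrm{Poisson}(\lambda_{it}), \qquad
  \lambda_{it} = \rho_{it}\,\epsilon_{it},$$

where $\epsilon_{it} = y_{i,t-1}$, the previous year's production,
enters as a known offset, so the modelled quantity $\rho_{it}$ is the
year-over-year production rate. The rate is log-linear:

$$\eta_{it} = \log \rho_{it}
  = \alpha + \gamma_i + \delta_t + \beta X_{it},$$

with $\alpha$ a grand intercept (the average log growth rate),
$\gamma_i \sim N(0, \tau_\gamma^{-1})$ an iid municipality effect,
$\delta_t$ a first-order random walk (RW1) over years with innovation
precision $\tau_\delta$, constrained to sum to zero for
identifiability, and $\beta$ the effect of a single climate covariate
$X_{it}$ in its original units. Each crop is paired with each covariate
in its own single-covariate model, which avoids instability from the
strong correlation among climate variables. Effects are reported as
$100(e^{\beta} - 1)$, the percent change in production per unit of the
covariate (per degree Celsius, per kPa, and so on) — see
`percent_change()`.

Priors: $\alpha$ and $\beta$ get mean-zero Gaussians with precision
0.001 (sd $\approx 31.6$ on the log scale — effectively flat over any
plausible growth rate); both random-effect precisions get a
$\mathrm{Gamma}(1, 5\times 10^{-5})$ hyperprior, the conventional vague
default for latent Gaussian models. A shape of exactly zero would make
this hyperprior improper, so the proper shape-1 member of the family is
used. Full conditionals of the precisions are conjugate Gamma
(`gibbs_update_precision()`).

Rows whose offset is zero are dropped rather than shifted by a
pseudo-count: when last year's production was nil the rate of change is
undefined, and inventing one would put prior mass on an arbitrary
scale. Covariates are never standardised, because the reporting scale
is "percent per unit".

## Yearly climate covariates

`aggregate_yearly()` reduces monthly climate variables to the eleven
yearly covariates the model uses: the yearly minimum of monthly minimum
temperature, the yearly maximum of monthly maximum temperature, and the
yearly mean per month of everything else. Monthly average temperature
is taken as the midpoint $(t_{\min}+t_{\max})/2$ — the standard
climatological choice when no direct average-temperature layer exists
— and then averaged over months. Aggregation is by calendar year with
no crop-calendar alignment, matching the yearly resolution of the
production data. Years with missing months are averaged over the
available months and flagged (`complete = FALSE`, `n_months`); a
variable entirely missing for a municipality-year becomes `NA`, never a
silent zero. No spatial interpolation or polygon averaging is
performed; a monthly value is whatever the source supplied per
municipality (for gridded sources, typically the cell at the
municipality's centroid).

`fit_trend_smoother()` supports descriptive national time series: it
fits polynomials of degree 1–4 in year by ordinary least squares and
keeps the AIC-minimising degree, with
$\mathrm{AIC} = n\log(\mathrm{RSS}/n) + 2(d+2)$. Polynomials are the
plainest reading of "four nested linear-in-parameters candidates", and
AIC is the usual automatic selector among them. Two numerical details:
fitting uses centred years (a raw quartic in calendar years is badly
conditioned) with coefficients re-expanded to the raw scale, and the
RSS entering the AIC is floored at the numerical noise level
($\sum y^2 \times 10^{-24}$) so that a series fitted *exactly* by
several candidates — a constant series, say — resolves to the most
parsimonious degree instead of letting roundoff pick a quartic. Note
that with a penalty of 2 per extra parameter, AIC retains a spurious
quartic term over a true cubic about 16–22% of the time; that is a
property of AIC itself, not of this implementation.

## Posterior computation

The reference for this model class is deterministic nested Laplace
approximation; `cropclim` instead pairs two independent engines and
uses their agreement as the correctness argument.

**MCMC (`sample_posterior()`).** A Metropolis-within-Gibbs sampler in
which every location update is a *Metropolized independence proposal
from a conditional-Laplace approximation*: the update finds the mode of
the parameter's full conditional by Newton iteration, proposes from a
Gaussian centred there with sd from the conditional curvature (inflated
by 1.2 so the proposal dominates the target's tails), and accepts with
the exact Metropolis–Hastings ratio including the proposal-density
correction. Concretely, per iteration:

* $\alpha$: one conditional-Laplace update, $O(1)$ given the cached
  sum of Poisson means;
* $\beta$: a conditional Newton solve (a few $O(n)$ passes) and
  independence draw;
* a joint *ridge* update that moves $\beta$ while compensating
  $\alpha$, $\gamma$ and $\delta$ for the covariate components they can
  absorb (the municipality means and year means of $X$), so the linear
  predictor changes only through the double-centred covariate residual.
  Without this move $\beta$ and $\delta$ share a narrow ridge — the
  year-mean component of the covariate is nearly collinear with the
  year effects — and componentwise samplers mix across it arbitrarily
  slowly;
* $\gamma_i$: all $N$ updates vectorised (they are conditionally
  independent given the rest), followed by a deterministic recentring
  that moves $\operatorname{mean}(\gamma)$ into $\alpha$;
* $\delta_t$: checkerboard updates (odd and even years alternately;
  under the RW1 prior each parity is conditionally independent given
  the other), with the sum-to-zero constraint re-imposed by projecting
  the mean into $\alpha$;
* $\tau_\gamma, \tau_\delta$: exact conjugate Gibbs draws.

Why independence proposals rather than tuned random walks? Because the
offset is *recursive* — this year's production is next year's offset —
municipality growth effects compound over the panel, and the count
scale can span four or more orders of magnitude across municipalities,
with a single municipality sometimes holding half the total weight.
Conditional posterior scales then differ so wildly that a global
step-size schedule adapted during warmup freezes at values that leave
some parameters unmixed. The conditional-Laplace proposals rescale
themselves every iteration, and for Poisson counts the Gaussian
approximation of a log-link conditional is excellent, so acceptance
rates stay near one without any tuning parameter. Chains start from
moment-based warm starts (empirical log-rates, an unweighted
least-squares slope for $\beta$) jittered at `init_jitter_sd` times
each parameter's conditional scale — overdispersed relative to the
posterior yet inside the basin the proposals can reach immediately.
Everything is driven by one seed; chains run sequentially from a single
stream, so a run is byte-reproducible.

**Laplace/MAP (`laplace_fit()`).** The independent cross-check: at
fixed precisions, damped Newton maximisation of the penalised
log-posterior of $(\alpha, \beta, \gamma, u)$, with $\delta = Cu$ in a
sum-to-zero basis, to a gradient tolerance of $10^{-8}$ *relative* to
the norm of the score's data term (with counts of order $10^9$ the
score is a difference of enormous terms, so an absolute criterion would
sit below floating-point resolution). Posterior sds come from the
inverse negative Hessian; the precisions maximise the Laplace
approximation of their marginal posterior over a log-scale Nelder–Mead
search. Near the optimum the line search is skipped (the remaining
improvement is below the objective's floating-point noise) and the
quadratically convergent pure Newton step is taken.

Diagnostics (`summarize_draws()`) are split-$\widehat R$ and a
rank-based effective sample size (autocovariances of rank-normalised
split chains, truncated by Geyer's initial monotone sequence). A
single-chain run reports $\widehat R$ as `NA` rather than a misleading
1.0.

## The synthetic-data generator

`simulate_panel()` draws from exactly the model above, so the whole
pipeline can be validated by parameter recovery. Defaults define the
package's reference study: $N = 150$ municipalities, $T = 14$ years,
$\alpha = 0.05$, $\beta = 0.025$, $\sigma_\gamma = 0.3$,
$\sigma_\delta = 0.1$, first-year production log-normal around 5000
tons (large enough that chains essentially never hit zero; a chain that
does stays at zero, and `build_design()` drops those rows exactly as it
would for observed data). The synthetic monthly climate is mean + linear
trend + sinusoidal seasonality + municipality offset + noise, with the
covariate expressed as an *anomaly* (mean 0, sd 1.5, trend 0.02 per
year): a centred covariate keeps the simulated panel numerically stable
over 14 years while still giving $\beta$ plenty of identifying
variation. Monthly minimum and maximum temperature share a midpoint
with a fixed 10-degree span, so their midpoint is the average
temperature by construction.

What the generator does *not* emulate: the marginal distribution of
real production data, spatial correlation between neighbouring
municipalities (the model's $\gamma$ is iid, so the generator's is
too), reporting artefacts, or crop calendars. Passing recovery tests
therefore demonstrates that the inference machinery is correct for the
stated model — not that the model is adequate for any particular real
data set.

One consequence of taking the recursive offset seriously deserves
emphasis: persistent municipality effects compound, so simulated
production is very heavy-tailed across municipalities, and a few
municipalities dominate the counts. The package treats that as a
feature — it stress-tests the samplers in the regime the model itself
implies — and it is why production is stored as doubles (Poisson means
beyond $10^9$ use a normal approximation whose relative error at that
magnitude is negligible).

## Reference validation study

The test suite and `scripts/acceptance.R` rerun, from scratch:

* record-count arithmetic: completing a sparse panel over 5 crops
  $\times$ 1121 municipalities $\times$ 14 years gives exactly 78,470
  rows;
* a likelihood oracle (100 random instances against independent
  Poisson log-pmf sums, tolerance $10^{-10}$) and a conjugacy oracle
  (Kolmogorov–Smirnov tests of 10,000 Gibbs precision draws against
  their closed-form Gamma laws);
* parameter recovery: 20 replicates of the reference study, fitted
  with 4 chains of 1000 warmup + 1000 retained draws; the 95% interval
  for $\beta$ must cover the truth in at least 17, with mean absolute
  error below 0.01 (observed: $\sim 10^{-4}$);
* null calibration: the same with $\beta = 0$;
* engine agreement: on 20-municipality, 5-year instances the Laplace
  mode of $\beta$ falls within half an approximate posterior sd of the
  MCMC mean in at least 9 of 10 replicates;
* end-to-end effect-scale recovery: a generative effect of
  $\log(1.0255)$ — a +2.55% change per covariate unit — is recovered
  through the full pipeline on the percent scale.

These problem sizes were chosen to exercise the exact reference
conditions of the recovery study while keeping a complete run of the
suite in the minutes range on a single core.

## Known limitations

* The RW1 year effect assumes consecutive, equally spaced years; the
  design builder only pairs consecutive calendar years, but a panel
  with large gaps yields a year index that the RW1 prior treats as
  adjacent.
* No overdispersion or zero-inflation: production is taken as a pure
  Poisson count given its offset, so extra-Poisson variability loads
  onto the random effects.
* No multiple-comparison adjustment across the crop $\times$ covariate
  sweep; the effect table reports each fit marginally.
* The Laplace engine's precision optimisation uses a local search; on
  pathological data it can settle on a local optimum, which is one
  reason it is the cross-check rather than the primary engine.
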