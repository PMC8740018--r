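---
title: "Fitting lognormal concentration distributions to censored microbial enumeration data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting lognormal concentration distributions to censored microbial enumeration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfufit)
```

## The problem

Plate-count enumeration of microorganisms in food reports a concentration in
CFU/g only when colonies can actually be counted.  With the classical 1:10
homogenate (25 g of sample in 225 ml of diluent) and 1 ml plated, a single
colony corresponds to 10 CFU/g, so the limit of quantification (LOQ) is
10 CFU/g; any sample with fewer organisms is reported as "not detected" (ND).
An ND result is *left-censored*: the concentration is known to lie below the
LOQ, but it is not zero.  Semi-quantitative surveys are coarser still and
report only a concentration class per sample (ND, 10–10², 10²–10³ CFU/g, ...),
i.e. *interval-censored* data.

Common practice either drops ND results or substitutes a fixed value (0,
LOQ/2, LOQ) before computing a mean and standard deviation.  Both distort the
estimates — dropping ND samples selects the upper part of the distribution
and biases the mean upward; substitution compresses the spread — and the
distortion grows with the censored share, which in routine food surveillance
can exceed 90%.  Quantitative microbial risk assessment consumes fitted
concentration distributions as exposure inputs, so these biases propagate
into risk estimates.

## The model

Concentrations are modelled as lognormal: the log10 concentration
$y = \log_{10}(x)$ is Normal$(\mu, \sigma)$, with both parameters in
log10 CFU/g.  Each sample contributes to the likelihood according to what was
observed:

* a quantified value $y_i$ contributes the density
  $\phi\!\left((y_i - \mu)/\sigma\right)/\sigma$;
* an ND sample contributes the probability below the censoring bound,
  $\Phi\!\left((b_0 - \mu)/\sigma\right)$ with $b_0 = \log_{10}(\mathrm{LOQ})$;
* a class $[l, u)$ contributes its probability mass
  $\Phi\!\left((u - \mu)/\sigma\right) - \Phi\!\left((l - \mu)/\sigma\right)$.

With $n$ quantified values and $m$ ND samples the likelihood is the familiar
censored-data product
$L(\mu, \sigma) = \Phi\!\left(\frac{b_0-\mu}{\sigma}\right)^{m}
\prod_{i=1}^{n} \frac{1}{\sigma}\phi\!\left(\frac{y_i-\mu}{\sigma}\right)$,
extended by the interval terms for class data.  `fit_enum()` maximises its
logarithm.

Working on log10 rather than natural log is a pure convenience: the normal
family is affine-equivariant, so a fit in any log base converts exactly to
any other, and both the inputs (decade classes) and the reported outputs
(log CFU/g) of this field are base-10.

## Numerical choices

Everything is computed in log space.  With $m \approx 1000$ censored samples
the literal product above underflows double precision long before the
optimum; the log-likelihood is immune.  The censored term uses the stable
log-CDF (`pnorm(..., log.p = TRUE)`), which stays finite for standardised
bounds far beyond $z = -30$.  Interval masses are computed as a difference of
CDFs evaluated on the nearer tail (upper-tail form when the class lies above
$\mu$), which preserves relative accuracy for classes far out in either tail;
if cancellation still yields a non-positive difference, the dominant tail
mass scaled by machine epsilon is used as a finite floor (bounded at −745
per observation, near the log of the smallest positive double).

Optimisation is over $(\mu, \log \sigma)$, making $\sigma > 0$ structural
rather than a constraint.  A Nelder–Mead simplex from a substitution start
point (exact values as-is, ND at $\log_{10}(\mathrm{LOQ}/2)$, classes at
their log-midpoint; $\mu_0$ = weighted mean, $\sigma_0$ = weighted
n-denominator SD floored at 0.05) is refined by BFGS, both at relative
tolerance $10^{-10}$ with at most 2000 iterations.  For a two-parameter,
log-concave problem this is robust and deterministic; the uncensored limit
reproduces the closed-form mean and n-denominator SD to $10^{-6}$ (verified
against an exhaustive grid search and against
`fitdistrplus::fitdistcens()` in the test suite).

The n-denominator SD (the MLE) is used everywhere, including the
censoring-free summary path, so all four sub-tool modes agree exactly when
censoring vanishes; the $n-1$ convention would differ by a factor
$\sqrt{n/(n-1)}$.

Confidence intervals are Wald intervals from the observed information: the
negative Hessian of the log-likelihood at the MLE, computed by central
finite differences in $(\mu, \sigma)$ with step
$10^{-5}\max(1, |\theta|)$, inverted and combined as
$\hat\theta \pm z_{0.975}\,\mathrm{SE}$.  No method is canonical for this
tool class; Wald is the standard MLE companion and is testable against the
closed forms $\hat\sigma/\sqrt{n}$ and $\hat\sigma/\sqrt{2n}$ in the
uncensored limit.  If the information matrix is not positive definite the
standard errors are reported as unavailable with a warning rather than
invented.  Profile-likelihood intervals are a deliberate non-goal.  The 5th
and 95th percentiles of the *fitted distribution*
($\mu \mp 1.645\,\sigma$) are reported separately from the confidence
intervals of the *parameters*; the two answer different questions and are
labelled distinctly in all reports.

## Identifiability

A dataset that is 100% ND carries no information about location and spread
separately: any $(\mu, \sigma)$ pushing essentially all mass below the LOQ
fits equally well.  `fit_enum()` therefore requires at least one
non-censored observation (and at least two observations overall) and raises
a structured error otherwise; presence/absence (qualitative) data are
unsupported for the same reason.  Right-censoring ("too numerous to count")
is likewise out of scope.

## Sub-tool modes

Datasets are classified the way bench tools organise them: QN_1
(quantitative, no ND), QN_2 (interval classes, no ND), QN_3 (quantitative
with ND), QN_4 (interval classes with ND).  QN_1 needs no MLE — the summary
is the closed-form mean and SD of the logs — while QN_2–4 route through the
maximiser.  The mode is derived from the data (censoring present ⇔ QN_3/4,
classes present ⇔ QN_2/4) and an explicitly requested mode that contradicts
the data is a usage error in the CLI.

## Two conventions for class data

The statistically efficient treatment of a class $[l, u)$ is its exact
probability mass, and that is the default (`convention = "interval"`).

Historical spreadsheet implementations of this analysis treated
semi-quantitative tables differently: each detected class was collapsed to a
point observation at the linear-scale class midpoint — 55 CFU/g for 10–10²,
550 for 10²–10³ — and, reading the classes as discrete plate-count ranges,
the ND class "fewer than 10 CFU/g" was censored at 9 CFU/g (counts 0–9)
rather than at 10.  `convention = "classic"` reproduces this treatment
exactly; it is what reproduces the published case-study estimates to their
printed precision (see `scripts/acceptance.R` in the source repository):

```{r conventions}
case1 <- enum_intervals(10^(1:5), 10^(2:6), c(258, 368, 234, 44, 2),
                        nd = 214, loq = 10, label = "total coliforms")
coef(fit_enum(case1, convention = "classic"))
coef(fit_enum(case1, convention = "interval"))
```

The two disagree visibly (here about 0.2 log10 in the mean) because the
midpoint convention places all mass of a decade class at a point
$\log_{10} 5.5 \approx 0.74$ above the class floor, whereas the fitted
normal density inside a wide class is asymmetric.  The interval convention
is the better statistical answer for grouped data; the classic convention
exists for continuity with historical results.  The conventions coincide for
purely quantitative data, where classic semantics do not apply.

## The simulator

`simulate_enum()` draws $n$ log10 concentrations from
Normal$(\mu^*, \sigma^*)$, censors below $\log_{10}(\mathrm{LOQ})$, and
either keeps detected values exactly (quantitative mode) or groups them into
classes (interval mode).  Simulated values above the last class edge are
clamped into the top class with a warning — mirroring the finite class range
of real report tables — rather than rejected, which would truncate the
distribution being studied.  Replicate $r$ of a study uses seed
$\mathrm{seed} + r$, so every study is exactly repeatable, and the
generator restores the caller's RNG state.

What the simulator emulates is the *reporting* process: lognormal
concentrations observed through an LOQ and optional decade classes.  What it
does not emulate: Poisson colony-count noise on the plate, between-lot or
between-day variability, measurement error in dilution, or departures from
lognormality.  Passing recovery tests therefore demonstrate that the
estimator inverts the censoring mechanism correctly, not that real
enumeration data are lognormal.

`recovery_study()` and `substitution_summary()` quantify the contrast that
motivates the method: at 30% censoring and $n = 2000$ the MLE's mean bias is
below 0.05 log10 in both parameters, while at 80% censoring dropping ND
samples overestimates the mean in essentially every replicate (both checks
run in the test suite).  The `"zero_excluded"` rule — substitute zero, then
exclude the undefined logs — is arithmetically identical to `"ignore_nd"`
and is provided under both names only because both phrasings circulate.

## Problem sizes used in the validation suite

The packaged checks fit the four case tables ($n = 1120, 1120, 100, 100$),
compare the optimiser with an exhaustive grid search (step 0.01 over
$\mu \in [-6, 8]$, $\sigma \in [0.02, 6]$) on twenty datasets of up to 30
samples, and run 200-replicate recovery studies at $n = 2000$.  These sizes
were chosen to make sampling error negligible relative to the tested
tolerances while keeping the whole suite interactive (well under a minute).

## Known limitations

* Class bounds are treated as half-open $[l, u)$ partitions; whether a
  boundary concentration belongs to the class above or below is
  unanswerable from published tables, but under a continuous model the
  assignment has zero probability mass and does not affect the MLE.
* Whether ND classes in published survey tables may include true zeros
  (absent organism) rather than sub-LOQ presence is likewise not stated in
  the sources; the continuous-lognormal treatment assumes sub-LOQ presence.
  A zero-inflated model would be the next step and is out of scope.
* Wald intervals are symmetric and can be poor for $\sigma$ at small $n$ or
  extreme censoring; the reported interval for $\sigma$ may then extend
  below zero and should be read as a diagnostic, not a hard bound.
* Bootstrap and Bayesian uncertainty quantification are out of scope.
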