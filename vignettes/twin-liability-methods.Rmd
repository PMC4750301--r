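---
title: "Twin liability-threshold analysis under competing risks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin liability-threshold analysis under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinrisk)
```

## The scientific problem

twinrisk analyses a dichotomous, strongly age-dependent endpoint — the
motivating example is total knee arthroplasty (TKA) for primary knee
osteoarthritis — in a classical twin design where follow-up is a fixed
administrative window (a surgery register opened in one calendar year and
queried in another), individuals enter the risk set at whatever age they
had when the window opened (delayed entry / left truncation), and death
competes with the endpoint.  The questions are the classical ones of twin
epidemiology: how much of the variance in liability is genetic (A, D),
shared environmental (C) and unique environmental (E); how concordance
and heritability evolve with attained age; and how sex modifies risk.

## The liability-threshold model

Each twin carries a latent liability $L \sim N(0, 1)$; the twin is
affected iff $L > \tau$, where $\tau = \Phi^{-1}(1 - K)$ and $K$ is the
prevalence (possibly sex-specific).  A twin pair is bivariate normal
with correlation set by zygosity:

$$\rho_{MZ} = a^2 + d^2 + c^2, \qquad
  \rho_{DZ} = \tfrac12 a^2 + \tfrac14 d^2 + c^2,$$

with $a^2 + d^2 + c^2 + e^2 = 1$.  MZ pairs share all additive,
dominance and common-environment variance; DZ pairs (same- and
opposite-sex) share half the additive and a quarter of the dominance
variance.  The probability that both members of a pair are affected is
the upper orthant mass $P(L_1 > \tau_1, L_2 > \tau_2)$, computed by
`bvn_orthant()` using Genz's Gauss–Legendre scheme (absolute error
around $10^{-15}$; naive quadrature or Monte Carlo is inadequate because
thresholds near 2.7 put orthant masses around $10^{-4}$).

`fit_tetrachoric()` maximizes the multinomial likelihood of a pair-count
table over $(\rho, \tau)$.  Same-sex double-entered tables have three
unordered cells and two free parameters, so the model is
just-identified: the two-stage estimator (thresholds fixed at the
marginal prevalence, one-dimensional search over Fisher-$z(\rho)$) and
the full ML coincide, which the tests exploit as a cross-check, and an
independent grid search over $\rho$ at step $10^{-3}$ serves as the
oracle.  Opposite-sex tables keep the ordered discordant split and two
sex-specific thresholds.

Descriptive identities (`falconer_H()`, `ace_from_correlations()`):
$H = \mathrm{clip}(2(\rho_{MZ} - \rho_{DZ}), 0, 1)$,
$A = 2(\rho_{MZ} - \rho_{DZ})$, $C = 2\rho_{DZ} - \rho_{MZ}$,
$E = 1 - \rho_{MZ}$.  Negative raw components are reported with a
boundary flag rather than silently clipped, so a constrained re-fit is a
conscious step.

## Biometric model fitting

`fit_model()` maximizes the (optionally weighted) bivariate-probit
likelihood: each pair contributes $w_1 w_2 \log P(\text{cell})$ with the
rectangle probability of its observed affection cell.  The model grid is
saturated (free $\rho_{MZ}$, $\rho_{DZ}$), ACE, ADE, AE, CE, DE and E;
A and D are never free together with C (classical twin data identify at
most three of the four components).  Sex enters either by
stratification (one threshold) or adjustment (sex-specific thresholds,
opposite-sex pairs pooled with same-sex DZ, one correlation per
zygosity class — no qualitative sex-limitation models).

Numerical choices:

* Components are parameterized by a softmax over the free set with E as
  reference.  This enforces nonnegativity and the unit total variance
  exactly, avoids optimizer failures at the boundary, and lets a truly
  null component converge to 0 smoothly.  Pairs are aggregated into
  weighted outcome cells before optimization, so the likelihood cost is
  independent of cohort size.
* Correlations in the saturated model are optimized on the
  $\tanh^{-1}$ scale; Nelder–Mead with two starting points (uniform
  split and a component-heavy start), relative tolerance $10^{-12}$.
* Rectangle probabilities are floored at $10^{-300}$ before the log, so
  the objective is never $-\infty$ for $|\rho| < 1$.
* Degrees of freedom count free variance components (the sum-to-one
  constraint excluded) plus free thresholds; AIC $= 2k - 2\log L$.
  Likelihood-ratio tests of a component on its boundary use the naive
  1-df chi-square and are conservative, which is noted in the
  comparison table rather than corrected.
* Confidence intervals, when requested, are percentile pair bootstraps
  (components and H re-estimated per resample); the weights are held
  fixed across resamples rather than re-estimated, a deliberate
  simplification that slightly understates weight-estimation
  uncertainty.

`heritability_by_age()` redefines affection as "event by attained age
$t$" and refits the chosen model along a grid of $t$ — cumulative-case
curves, matching how age-resolved heritability is usually displayed for
register endpoints.  Grid ages with fewer than `min_affected` (default
10) affected members are reported missing rather than fitted.

## Competing risks on the age scale

All time-to-event machinery uses attained age, with entry age encoding
left truncation: an individual is in the risk set at age $t$ iff
$\text{entry} < t \le \text{exit}$.  `aalen_johansen()` estimates the
cause-specific cumulative incidence
$F_c(t) = \sum_{t_j \le t} S(t_j-) \, d_{c,j} / n_j$ with Kaplan–Meier
overall survival over both causes and an Aalen-type variance
(implemented with cumulative sums, so curves on $10^5$ records cost
well under a second).  Ties at one age are resolved events-first:
a twin censored at $t$ is still at risk at $t$; the two causes share
the same $S(t-)$.  With no competing cause the estimator collapses to
$1 - \text{KM}$ exactly, and `survival::survfit` is used as an
independent oracle in the test suite.

`censoring_survival()` is the role-swapped Kaplan–Meier (censoring as
the event), and `ipc_weights()` forms inverse-probability-of-censoring
weights: a complete observation (event or death at age $T$) weighs
$1/\hat G(T-)$; an administratively censored twin contributes as a
non-case with weight $1/\hat G(\text{end}-)$.  Death is treated as a
complete observation for the liability outcome — a twin who dies
without the endpoint is a known lifetime non-case — so the weights
correct administrative censoring only.  Weights are capped (default 20)
with the number of capped weights reported; the cap protects small
strata against positivity failures at old ages.

`concordance_function()` estimates the age-indexed proband-wise
concordance
$\hat P(\text{both affected by } t) / \hat P(\text{named member
affected by } t)$, with IPC-weighted pair and individual estimators and
a pair bootstrap (resampling pairs, not individuals, to respect
within-pair dependence) for the band.  The marginal curve — the
individual estimator itself — is the risk a co-twin would face if twins
were genetically unrelated, and is the natural reference line.

## What the synthetic cohort emulates

`simulate_cohort()` generates the world the analysis assumes: bivariate
normal liabilities with the zygosity-implied correlation, sex-specific
thresholds from lifetime risks, and then a minimal temporal overlay:

* susceptibility (whether a twin ever reaches the endpoint) is decided
  by the liability threshold; **age at onset among susceptibles is
  independent of liability magnitude**, Weibull with shape 6 and scale
  85 years, making onset rare before 50 and steeply rising after;
* death is an independent Gompertz competing event
  ($h(t) = a e^{bt}$, $a = 10^{-4}$, $b = 0.085/\text{yr}$, a standard
  adult-mortality shape);
* both members of a pair share a birth year (they are twins), drawn
  uniformly from 1905–1985, so entry ages at the 1997-analogue window
  start span 12–92; the window closes 13 years later;
* twins dead before the window never enter; twins whose onset precedes
  entry (prevalent cases) are excluded by default because an
  arthroplasty register only records surgeries inside its window
  (`include_prevalent = TRUE` exists to study the resulting bias).

`default_scenario()` fixes the registry scale: 9,998 MZ, 17,339
same-sex-DZ and 19,037 opposite-sex-DZ pairs (46,374 pairs, 92,748
twins), A/C/E = 0.18/0.61/0.21, and lifetime risks 0.082 (F) / 0.055
(M).  The risks were calibrated once so the within-window case fraction
is about 0.6% of twins with a female:male case ratio near 1.64, the
composition of the motivating register linkage, and then frozen.

Features of real data the generator does **not** emulate: calendar
trends in surgery rates, BMI and occupational covariates, shared
onset-age frailty beyond the liability correlation, zygosity
misclassification, and genotype-environment covariance.  A green test
therefore establishes internal consistency of the estimators under the
model's own assumptions, not robustness to these violations.

## What the windowed analysis estimates (a deliberate red test)

One acceptance check is left failing on purpose, because it encodes an
idealization the stated world cannot meet.  The windowed case status —
"surgery recorded inside the 13-year window" — is a *thinned* version
of the lifetime liability outcome: a susceptible twin becomes a case
only if onset happens to fall inside the window.  Thinning a
dichotomized bivariate normal attenuates its tetrachoric correlation;
with a thinning probability around 0.33 the closed-form calculation
sends $\rho_{MZ} = 0.79$ to about 0.50 and $\rho_{DZ} = 0.70$ to about
0.44, and a 500,000-pair simulation of the weighted ML fit converges to
exactly those values.  Consequently C is biased downward by roughly
0.30 and E upward by the same amount, while the MZ–DZ *difference* —
hence A and the broad-sense heritability — is approximately preserved.
Inverse-probability-of-censoring weighting corrects unequal follow-up
among observed subjects; it cannot resurrect events that fall outside
the register's window.  The practical reading: windowed twin-register
analyses of late-onset surgical endpoints estimate the variance
decomposition of *windowed incidence*, whose genetic component tracks
the lifetime one far better than its environmental split does.

## Other design decisions

* "Both alive at entry" (the pair-level filter used for the
  concordance/tetrachoric table) drops pairs in which a member's death
  precedes window start; since such individuals never enter a valid
  cohort file, the filter is a no-op on simulator output but is kept
  for externally assembled cohorts.
* The within-pair independence screen is a Pearson chi-square on the
  double-entered table (twins treated as exchangeable, not
  independent): a descriptive screen.  A likelihood-ratio alternative
  on $\rho$ (`independence_test_lr()`) is provided; published p-values
  for such screens are not comparable across choices of test, so none
  are asserted.
* The model-implied case-wise concordance per zygosity is evaluated at
  the pooled-prevalence threshold
  ($\text{cwc} = P(L_1>h, L_2>h)/\Phi(-h)$) in sex-adjusted mode;
  reporting it per sex would double the table width for little insight.
* Bootstrap replicate counts default low in the pipeline (50) and are
  configurable; published-scale inference would use 500+.
* The opposite-sex tetrachoric correlation is excluded from acceptance:
  the printed value for the motivating data is not recoverable from the
  printed counts under equal thresholds (the oracle gives about 0.30
  versus the printed 0.36), indicating unprinted sex-specific margins.

## Known limitations

Extended twin-family designs (needed to separate shared environment
from genotype-environment covariance), sex-limitation models with a
free opposite-sex correlation, Fine–Gray regression, and
covariate-adjusted liabilities beyond sex are out of scope.  The IPW
estimand caveat above is the dominant interpretive limitation for
windowed registers.
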