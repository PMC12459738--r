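---
title: "Growth-curve analysis of a two-arm game-intervention trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve analysis of a two-arm game-intervention trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgcmtrial)
```

## The problem

Leisure online games reach very large populations, and in-game prompts
(ring a friend's doorbell, customize your avatar) can deliver behavioural
activation and exposure-style interventions at negligible marginal cost.
Evaluating such an intervention takes a two-arm randomized trial with
repeated symptom questionnaires — depression (QIDS) and social anxiety
(Brief LSAS, administered for both the in-game and the face-to-face
community) — measured at baseline and after 1, 2 and 3 months, plus game
behaviour logs as manipulation checks. Three statistical features dominate
the design: symptom change is fast early and slow late; participants skip
questionnaire waves; and behaviour counts are heavy-tailed. This package
implements the corresponding analysis — a latent growth curve model (LGCM)
on log-transformed time, estimated by full-information maximum likelihood
(FIML) — together with a synthetic trial generator so every stage can be
validated without access to any real participant data.

## Model and assumptions

Participant $i$ at wave $t$ has outcome

$$Y_{it} = B_{0i} + B_{1i} F_t + \varepsilon_{it}, \qquad
\varepsilon_{it} \sim N(0, \sigma^2_{e}),$$

where the latent intercept and slope are linear in the arm indicator
$G^{exp}_i$ and the gender indicator $G^{female}_i$ with bivariate-normal
individual deviations $(u_{0i}, u_{1i})$. The time loadings are
$F_t = \log_2(\text{months}_t + 1)$: 0, 1, 1.585, 2 for waves at 0, 1, 2, 3
months. The basis is concave in months, so equal score drops per unit of
$F$ translate into a large first-month improvement that then decelerates —
the shape typically seen in symptom trajectories. `b1exp`, the arm effect
on the slope, carries the entire intervention effect; under the model the
arm difference in means at the final wave is $2\,b_{1exp}$.

Assumptions worth stating explicitly: outcomes are treated as continuous
and conditionally Gaussian; the residual variance is shared across waves
(homoscedastic, a single $\varepsilon_{it}$ term — a wave-specific variant
was considered and rejected to keep the parameter count at ten, since
four-wave data identify wave-specific residuals only weakly once a free
intercept–slope covariance is present); the intercept–slope covariance is
estimated freely by default (`lgcm_spec(cov01 = FALSE)` fixes it at zero);
and missingness may depend on observed data but not on the unobserved
values (MAR), which is what makes the FIML estimates consistent.

## FIML numerics

Each participant contributes the multivariate-normal log-density of the
waves they actually completed, evaluated under the implied sub-mean and
sub-covariance; participants with no observed waves contribute exactly 0.
Three numerical choices matter:

* **Jitter.** `1e-4` is added to the diagonal of every observed
  sub-covariance immediately before inversion, keeping it positive
  definite. The same jitter is applied in all internal oracles and in the
  reported likelihood, so comparisons are exact rather than approximate.
* **Pseudo-inverse fallback.** If the jittered matrix is still singular,
  an eigendecomposition pseudo-inverse is used, with a pseudo-determinant
  over eigenvalues above `1e-12`; null directions are dropped from both
  the quadratic form and the dimension term. This keeps the likelihood
  finite for degenerate parameter values instead of erroring mid-search.
* **Pattern grouping.** Participants are grouped by missingness pattern so
  each sub-covariance is factorized once per pattern; means are vectorized
  over participants. One full-data fit at n = 1000 takes well under a
  second.

Optimization is bounded quasi-Newton (L-BFGS-B). Internally the variance
components are carried as log standard deviations and the covariance as
atanh(correlation): this enforces positive semidefiniteness of the
random-effect matrix throughout the search and stabilizes the numerical
Hessian, while the lower bounds on the log-SD coordinates implement the
variance floor of `1e-8` on the natural scale. (A direct natural-scale
parameterization with box bounds was tried first; it permits transiently
indefinite random-effect matrices, which the transformed scale rules out
by construction.) Starting values: intercept at the grand mean of observed
baseline values, slope terms at 0, the observed outcome variance split
equally across the free variance components, correlation 0. Convergence
uses `factr = 1e4` — tight enough that complete-data estimates agree with
an independent mixed-model fit (lme4, ML) to about `1e-3`. Standard errors
come from the inverse of the central-difference Hessian (step
`1e-4 (1 + |\theta|)`), with a jitter-plus-pseudo-inverse fallback when it
is singular; Wald statistics are `beta/se` and CIs use `1.959964 * se`.

## Posterior sampling and fit criteria

The sampler targets the same FIML likelihood times a proper prior: normal
(0, 10 sd(y)) on fixed effects, half-normal(0, 5 sd(y)) on SD-scale
variance parameters, uniform(−1, 1) on the random-effect correlation.
It is a Haario-style adaptive random-walk Metropolis: during burn-in the
proposal covariance tracks the chain history (scaled by $2.38^2/d$) and a
Robbins–Monro rule steers acceptance toward 0.234; both freeze at the end
of burn-in so the retained draws come from a fixed kernel. Chains get
deterministic per-chain seeds derived from the user seed. Convergence is
summarized by split-chain $\widehat R$ (each chain halved; ratio of pooled
to within variance), which handles a zero-within-variance chain by
reporting infinity rather than failing.

WAIC and LOO are computed from the per-participant log-likelihood recorded
at every retained draw. WAIC uses the log-mean-exp pointwise predictive
density minus the pointwise variance penalty; LOO uses importance sampling
with weights $1/p(y_i\mid\theta_s)$ truncated at $S^{3/4}$ times their
mean, flagging participants whose largest normalized weight exceeds 0.7.
Both are reported on the elpd scale *and* the deviance scale
($-2 \cdot$ elpd), never as a bare signed number: published tables in this
area sometimes print negative criterion values whose sign convention is
ambiguous, and keeping both scales explicit avoids that ambiguity. Point
estimation and Wald inference come from the ML path; $\widehat R$, WAIC
and LOO from the sampler — two routes over one likelihood.

## Questionnaire scoring

QIDS has 16 items on a 0–3 scale but is scored over 9 domains (sleep
group, appetite/weight group and psychomotor pair each contribute their
maximum), giving the 0–27 metric on which the clinical cut-off of 6 is
defined; `score_qids()` implements that rule, with a plain-sum option for
sensitivity checks only. The Brief LSAS is taken as 14 situations each
rated for fear and avoidance (0–3), raw total 0–84, following the
convention of the full instrument; since only the 24/14 rescaling and the
cut-off of 30 are externally fixed, the raw-metric assumption is a
documented choice, not a certainty. `adjust_lsas()` returns the unrounded
rational value and classification compares it exactly against 30 (so a raw
17.5 sits exactly on the cut-off). Behaviour counts are analysed as
`log2(count + 1)`: zero maps to zero and the transform inverts exactly on
integers.

## Effect sizes and baseline statistics

The intervention effect size is the SMD of change scores: arm difference
in mean (wave 4 − wave 1) change divided by the pooled SD of those
within-participant changes (n − 1 SDs, pooled with n − 1 weights). The
denominator is deliberately the SD *of the change scores*, not of the raw
scores — the quantity described alongside the formula in trial reports —
and on complete data the raw-change computation and the summary-statistic
formula agree to machine precision. Cross-sectional Cohen's *d* is
reported unsigned by default (as baseline tables print it) with a signed
variant. The 2×2 chi-square is uncorrected Pearson by default, so
$\phi^2 N = \chi^2$ holds exactly, with a Yates option (trial baseline
tables are often Yates-corrected, so both conventions are first-class). Change-score
correlation matrices use pairwise-complete Pearson correlations with
two-sided p-values, starred at .05/.01, and refuse cells with fewer than
3 pairs.

## The synthetic trial generator

`generator_config()` defaults define the emulated study conditions: arms
of 548 and 557, female proportion 0.7475, age 23.68 (SD 10.44) truncated
to 9–82, four waves at 0/1/2/3 months. The default growth truths mirror
the magnitudes of the reported tables: baseline depression mean ≈ 8.4 with
SD ≈ 6.05 (decomposed as `var_e0 = 25`, `var_e2 = 11.6`), intervention
slope `b1exp = −0.319`, and `var_e1 = 1.2` — a decomposition chosen (once)
so that the implied change-score SMD,
$2 b_{1exp} / \sqrt{4\,var_{e1} + 2\,var_{e2}}$, is −0.12, matching the
effect size scale of the trial this design emulates. `implied_smd()`
exposes that arithmetic. Social anxiety truths are set analogously
(baseline SDs ≈ 19 and ≈ 23). Counts default to the lognormal-on-log2
family — `count = round(2^L − 1)` with normal $L$, the analysis transform
inverted, with per-arm per-wave means 8.07/7.93/7.29/6.65 (bell,
experimental arm) etc. and a within-person intraclass correlation of 0.6 —
with a discrete power-law alternative whose exponent is a free parameter,
since only the qualitative tail behaviour is externally known. An optional
coupling makes the bell-count change correlate at a target $\rho$ with one
outcome's change by construction (it rebuilds the wave-4 innovation from
the realized standardized outcome change; keeping the wave-4 marginal SD
intact restricts $|\rho| \le 1/\sqrt2$). Dropout is wave-wise MCAR with
defaults (0, 0.10, 0.15, 0.20) — no per-wave response rates are externally
fixed for this design, so these are a realistic choice for a compensated
online panel, made once — plus an MAR mode in which the missingness odds
increase with the current depression score, for FIML stress tests.
Completion bonuses are Binomial(3, 0.73) in both arms (the experimental
completion rate assumed equal to the waitlist lottery rate), and the
reward schedule 500/200/200/500 JPY plus 3 × 500 JPY bonuses caps
compensation at 2900 JPY.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: questionnaire totals are continuous Gaussian
draws, without the integer grid, floor/ceiling effects, or skew of real
QIDS/LSAS scores; count distributions are calibrated in location and
spread, not to any real tail exponent; dropout is independent across waves
(no monotone attrition); and arm sizes are fixed rather than realized from
randomization (use `assign_arms()` for the latter). Recovery results on
these data demonstrate correctness of the estimator under its own
assumptions, not robustness to their violation.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:
closed-form univariate densities and a dense solve/determinant evaluation
for the complete-data likelihood (1e-8); brute-force numerical integration
over the missing coordinate for the FIML marginalization (1e-10); a
coarse-grid-plus-polish search for tiny-instance optima (1e-4 in
log-likelihood); lme4 as an independent mixed-model fit on complete data;
and hand-evaluated 3×2 matrices for WAIC/LOO (1e-12). Simulation checks
use 200 replicated trials at n = 500/arm for bias (< 0.02) and 95% CI
coverage (93–97%) of `b1exp`, n = 5000/arm for SMD recovery within 3
Monte-Carlo SEs, and a 60+60-participant model for sampler diagnostics
($\widehat R \le 1.01$ with 2 × 8000 iterations). These sizes make the
whole suite run in a few minutes while leaving Monte-Carlo error well
below the tolerances checked.

## Limitations

Single outcome per fit (no multivariate growth or cross-outcome
covariance); linear-in-$F$ trajectories only; no survey weights or
clustering; no multiple-imputation alternative to FIML; no robust/sandwich
standard errors; the sampler is a random-walk kernel, adequate for a
10-parameter posterior but not for much larger models. None of the
generator defaults is an assertion about any real trial's data — they are
working values that make demonstration runs live on a realistic scale.
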