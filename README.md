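# lgcmtrial

Latent growth curve analysis of two-arm randomized trials with repeated
questionnaire outcomes, built for the setting of in-game mental-health
interventions: two arms (~550 participants each), four measurement waves at
0/1/2/3 months, depression (QIDS, 0–27) and social anxiety (Brief LSAS,
rescaled to the 24-item metric) as outcomes, heavy-tailed in-game behaviour
counts as manipulation checks, and wave-wise dropout handled by
full-information maximum likelihood (FIML) rather than listwise deletion.

## The model

Participant *i* at wave *t* follows

```
Y[it] = B0[i] + B1[i] * F[t] + e[it],        e[it] ~ N(0, var_e2)
B0[i] = b00 + b0exp * Gexp[i] + b0female * Gfemale[i] + u0[i]
B1[i] = b10 + b1exp * Gexp[i] + b1female * Gfemale[i] + u1[i]
```

with `(u0, u1)` bivariate normal (variances `var_e0`, `var_e1`, covariance
`cov_e01`) and a log-transformed time basis `F[t] = log2(months + 1)` —
0.000, 1.000, 1.585, 2.000 for waves at 0, 1, 2, 3 months — encoding
fast-then-slow symptom change. `b1exp`, the arm effect on the slope, is the
intervention effect. Estimation maximizes the observed-data likelihood
(each participant contributes the normal density of their observed
sub-vector; a `1e-4` diagonal jitter and an eigen pseudo-inverse keep the
computation stable), with Wald tests and 95% CIs from the numerical
Hessian. A random-walk Metropolis sampler over the same likelihood supplies
split-chain Gelman–Rubin R-hat, WAIC and importance-sampling LOO. The
intervention effect size is the standardized mean difference (SMD) of
wave-4 minus wave-1 change scores, standardized by their pooled SD
(Cohen's *d* on changes).

A seeded synthetic-trial generator (`generate_trial()`) draws complete
trials with this exact structure — including power-law-like bell-ring and
avatar-customization counts analysed as `log2(count + 1)`, completion-bonus
and lottery rewards, and MCAR or MAR dropout — so the whole pipeline is
testable without access to any real trial data.

## Worked example

```r
library(lgcmtrial)

cfg <- generator_config(seed = 2026)   # defaults: arms 548/557, 4 waves
dat <- generate_trial(cfg)
fit <- fit_ml(dat, outcome = "qids")
fit
#>      term   beta    se   ll95   ul95   wald pvalue
#>       b00  7.763 0.395  6.989  8.537 19.655  0.000
#>     b0exp  0.094 0.356 -0.604  0.792  0.263  0.793
#>  b0female  0.622 0.413 -0.188  1.433  1.505  0.132
#>       b10 -0.232 0.178 -0.580  0.116 -1.307  0.191
#>     b1exp -0.486 0.160 -0.800 -0.172 -3.037  0.002
#>  b1female -0.088 0.186 -0.453  0.276 -0.474  0.635

smd_change(change_scores(dat[dat$arm == "experimental", ], "qids"),
           change_scores(dat[dat$arm == "waitlist", ], "qids"))
#> [1] -0.1319881
```

`b1exp = -0.486` (95% CI -0.800 to -0.172, Wald -3.04, p = .002) is the
estimated extra monthly-log-time decline in depression score in the
experimental arm — here recovering the generator's truth of -0.319 within
sampling error. The change-score SMD of -0.13 matches the effect size the
generator's default truth implies (-0.12). `run_pipeline()` wraps
simulation, baseline tables, per-outcome fits, SMDs and change-score
correlation matrices into one report directory;
`sample_posterior()` adds R-hat/WAIC/LOO diagnostics for the same model.

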