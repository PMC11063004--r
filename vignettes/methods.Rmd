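---
title: "Models and methods: decision parameters, attention problems, and latent change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ddmlcs` implements an analysis chain for longitudinal two-choice response
data and parent-rated attention problems: trial-level quality control,
drift-diffusion parameter estimation (hierarchical Bayesian or closed-form
EZ), and multigroup latent change score (LCS) structural equation models
with sex-equality constraint tests. Because the motivating data source is a
restricted-access developmental cohort, the package ships a first-class
synthetic-data module with known ground truth; every estimation stage is
validated by parameter recovery against that truth.

## The decision model

A two-choice decision is modeled as a Wiener diffusion between absorbing
boundaries at 0 and `a` (decision threshold), starting at relative position
`z` (bias), accumulating evidence at drift `v`, with non-decision time `t`
added to the first-passage time. The diffusion scale is fixed at 1; this is
the usual identifiability convention, and the EZ formulas are rescaled
accordingly. Data are stimulus coded: the accumulator measures "rightward"
evidence, the upper boundary is a rightward response (coded 1), and the
effective trial drift is `+v` for rightward and `-v` for leftward stimuli.
A single group-level parameter `sz` (total range of uniform trial-to-trial
variability in `z`) lets the model produce fast errors.

The first-passage density is evaluated by the standard series
representations in normalized time, switching between the small-time and
large-time expansions by the usual truncation-count criterion at tolerance
`1e-10`. With `sz > 0` the density is averaged over the starting-point
range by fixed-node Gauss-Legendre quadrature (11 nodes in the user-facing
density; the MCMC sampler uses 5 nodes internally, which agrees with a
21-node reference to below `1e-6` over the parameter ranges the package
generates — far below Monte Carlo error). An Euler-Maruyama simulator
(`dt = 1e-4` for oracle use; coarser steps are accepted where only
qualitative agreement is needed, e.g. posterior predictive replicates at
`dt = 1e-3`) serves as the brute-force check on the analytic density and as
the engine for posterior predictive checks; the simulator only needs to
converge to the model, not to be exact.

The closed-form forward map `ddm_moments()` (accuracy, mean and variance of
correct RTs under an unbiased diffusion) and its inversion `ez_fit()`
implement the EZ estimator. Two numerical choices matter: perfect or
chance-level accuracy is edge-corrected by half a trial (`1 - 1/(2n)`,
`0.5 + 1/(2n)`) before the logit, and the closed forms for the RT moments
suffer catastrophic cancellation as `v -> 0` (numerators are `O(c^3)`
differences of `O(1)` terms, `c = a v`), so a series expansion takes over
below `|c| = 2e-3`, accurate to ~1e-9 relative at the switch point.

## Quality control

The cleaning rules operate in a fixed order: one randomly selected subject
per family; removal of sessions with incomplete trial fields; exclusion of
sessions with go-trial accuracy below 60%; removal of trials faster than
200 ms. Both thresholds are strict inequalities — a session at exactly 60%
or a trial at exactly 200 ms is retained — and accuracy is computed before
fast-trial removal, matching the flow-chart order. Every step reports
`input = retained + removed`; `qc_report()` refuses to construct a report
that violates conservation. After estimation, the analysis panel keeps
subjects with data on at least one timepoint for *every* main variable
(each decision parameter and the attention score).

## Hierarchical Bayesian estimation

Sessions are randomly partitioned into batches (default batch size ~110,
mirroring the ~8700/80 ratio of the motivating design) and each batch is
fitted separately: session-level `v`, `a`, `t`, `z` drawn from group-level
normals on transformed scales (log for `a`, logit for `z`), one shared
`sz`. Priors are weakly informative documented constants: normal group
means (`v ~ N(2, 3^2)`, `log a ~ N(log 1.5, 1)`, `t ~ N(0.3, 0.5^2)`,
`logit z ~ N(0, 1)`), half-normal spreads (scales 2, 1, 0.3, 1), uniform
`sz` on its feasible range. The non-decision hierarchy is a normal on the
natural scale; its truncation at zero sits several prior SDs from the mass
and is ignored in the group-mean update.

The sampler is Metropolis-within-Gibbs with the full sweep in C++ (all
randomness through R's RNG, so runs are reproducible from `set.seed`):

- per-session blocked updates of `(v, log a, t, logit z)` using
  adaptive-Metropolis proposals — the empirical 4x4 covariance of each
  session's draws is accumulated during burn-in and scaled by `2.38^2/4`;
  three sweeps per iteration, since session updates are cheap relative to
  the global step and they limit the effective sample size;
- conjugate Gibbs draws for group means and random-walk updates on the log
  group spreads;
- a univariate slice sampler for `sz` on its full conditional. `sz` is
  weakly identified and nearly uncorrelated with the other parameters, so
  exact conditional draws give essentially lag-one mixing where a random
  walk was the convergence bottleneck.

All step sizes adapt only during burn-in. Defaults are three chains of
3000 samples with 2000 discarded; the validation runs in this package use
3x1500 with 1000 burn-in on 40 sessions of 300 trials, which completes in
a few minutes on one CPU and passes the classic (non-split, two-term)
Gelman-Rubin screen at 1.1 on every parameter. Screening is applied per
parameter: a flagged parameter becomes missing in the point estimates,
other parameters of the same session are kept. Posterior predictive checks
re-simulate each session from randomly drawn posterior parameter values and
compare observed accuracy and RT quantiles with their predictive intervals.

## Latent change score models

Models are held in RAM form (path matrix, covariance matrix, mean vector
over observed plus latent variables). The latent change `d` is defined by
fixed unit loadings (`follow-up = baseline + d`) and a zero follow-up
residual. In the univariate model the baseline-change dependence is a free
covariance (reported standardized, as a correlation); the bivariate model
instead uses self-feedback regressions `beta` plus the four cross-domain
parameters: baseline covariance `phi`, couplings `gamma1` (attention
baseline to change in the decision parameter) and `gamma2` (the reverse),
and the change residual covariance `rho`. Centred covariates enter the
baseline equations only, with means fixed at 0 and free
variances/covariances; with three covariates this gives the two-group
univariate model 12 degrees of freedom (40 moments minus 28 free
parameters) and the bivariate model 18. All substantive parameters are
group-specific unless explicitly constrained.

Estimation is full-information maximum likelihood: each row contributes the
multivariate-normal log density of its observed subset at the model-implied
moments. Rows are grouped by missingness pattern purely as a speed-up — a
unit test verifies equality with the naive per-row evaluation to `1e-10`.
The saturated reference model is fitted by an EM algorithm for the MVN mean
and covariance under ignorable missingness (closed form when data are
complete); the null model (free means and variances, zero covariances)
separates per variable and is closed-form even under missingness.
Optimization uses `nlminb` from moment-based starting values with jittered
multistarts; standard errors come from the inverse observed information
(numerical Hessian). Robust (sandwich/scaled) corrections are deliberately
not implemented: the synthetic data are multivariate normal, so plain and
robust ML coincide in everything this package can test; the estimator
boundary is documented so a sandwich extension can be added without
touching the model code.

Fit indices follow the conventional definitions: `CFI = 1 - max(T-df,0) /
max(T0-df0, T-df, 0)`; `RMSEA = sqrt(G) * sqrt(max(T-df,0)/(df N))`
(multigroup convention); SRMR averages squared standardized residuals of
covariances and means against the saturated estimates, weighting groups by
sample size. A just-identified model has `RMSEA = 0`, `CFI = 1` by
definition. Sex-equality tests constrain one parameter at a time across
groups and compare likelihood-ratio statistics (`df = 1` for two groups);
under a true null the test is calibrated — the acceptance suite verifies a
rejection rate of 5% (within Monte Carlo error) over 500 simulated panels.

## The synthetic cohort

The generator's defaults are the study conditions: ~300 go trials per
session at two timepoints two years apart, baseline age from a truncated
normal (mean 9.9, SD 0.6), 47.7% female, 15% of subjects in sibling pairs
(one is later dropped at random), 8% near-chance (non-compliant) subjects,
1.2% uniform fast-guess contaminant trials (RT 0.05-0.5 s), and 29%
follow-up attrition, missing completely at random. FIML's ignorability
assumption is thereby satisfied by construction; the package does not model
informative dropout. Latent values are drawn from the LCS equations
themselves with generative parameters on the scale of published
large-cohort estimates for this age range (drift baseline means 2.742 and
2.630 for females and males, attention-problem baselines 2.37 and 3.50,
negative drift-attention couplings; threshold and non-decision time are
generated with null couplings). Covariates are independent standard
normals (income, one genetic-ancestry factor score) and centred age; their
true effects on the baselines are zero, which the fitted covariate
regressions should and do recover.

Attention items use a cumulative-threshold model: 20 thresholds equally
spaced at 0.5..19.5 split across 10 three-category items, each item cut at
its thresholds after adding small item-specific normal noise (SD 0.5). With
the latent score on the 0-20 sum scale the item sum is approximately
`round(latent)` truncated to [0, 20] — monotone in the latent by
construction, with realistic right skew and a floor at zero. Two
consequences are documented rather than hidden: sum scores truncate below
zero (as real instrument scores do), and scores estimated from ~300 trials
or from items carry measurement noise that inflates observed variances
relative to the latent truth. Exact 3-SE parameter recovery is therefore
asserted where it is a theorem — on panels generated directly from the LCS
equations — while the end-to-end pipeline (trials -> QC -> EZ -> items ->
LCS) is validated on means and on the qualitative headline pattern:
negative baseline correlation and negative correlated change for drift vs
attention, null couplings for threshold and non-decision time.

## Problem sizes and numerical choices

Validation runs use: 40 sessions x 300 trials with chains 3x1500 (1000
burn-in) for hierarchical recovery and posterior predictive coverage;
n = 4000 per sex group for LCS recovery with and without 10% MCAR
attrition; 500 replicate panels of n = 500 per group for null calibration
of the 1-df constraint test; a 100-point grid for the EZ round trip; and 20
parameter sets for density conservation. Degenerate inputs are handled
explicitly: `rt <= t` yields zero density (not an exception), below-chance
sessions are estimation errors in EZ, non-positive-definite implied
covariances are likelihood penalties during optimization, and ties at QC
boundaries are retained by the strict-inequality convention.

## Known limitations

No inter-trial variability in drift or non-decision time (only
starting-point variability is modeled); no stop-process race model — only
go trials are analysed. The SEM engine covers exactly the univariate and
bivariate two-timepoint change-score shapes, not a general SEM language.
Attrition is MCAR only. Robust standard errors are a documented extension
point, not a feature. The bias parameter `z` and `sz` are estimated but not
surfaced in default report tables, since stimulus direction is a nuisance
dimension in this design.
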