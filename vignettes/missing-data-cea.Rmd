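---
title: "Pattern-mixture sensitivity analysis for cost-effectiveness with missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-mixture sensitivity analysis for cost-effectiveness with missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ceamiss)
```

## The problem and the model

Trial-based cost-effectiveness analyses routinely lose a fifth of their
quality-of-life (QoL) questionnaires and close to half of their cost
records. Whether the conclusion survives depends on an assumption that the
data cannot check: are the missing values like the observed ones given
covariates (MAR), or systematically different (MNAR)? `ceamiss` treats
that difference as a model parameter with an expert-informed prior, and
reports decision quantities whose uncertainty includes it.

The joint model has two linked parts. The repeated QoL scores of patient
$i$ in arm $k$ follow an arm-specific bivariate normal,

$$(\mathrm{QoL}_{i1}, \mathrm{QoL}_{i2}) \sim
  \mathrm{BVN}(\mu_i, \Sigma_k), \qquad
  \mu_{ij} = \eta_{jk} + \beta_{aj}\,\mathrm{age}_i +
  \beta_{sj}\,\mathrm{sex}_i + \beta_{hj,\,\mathrm{hardman}(i)}
  + (1 - R_{ij})\,\Delta_{jk},$$

where $R_{ij}$ indicates observation and $\Delta_{jk}$ is the
pattern-mixture offset: the mean difference between missing and observed
values. QALYs are the duration-weighted combination
$\mathrm{QALY}_i = w_1 \mathrm{QoL}_{i1} + w_2 \mathrm{QoL}_{i2}$ with
default weights $(1/2,\, 3/8)$ for assessments at 3 and 12 months, taken
as given. Costs enter through a conditional regression,

$$\mathrm{Cost}_i \mid \mathrm{QALY}_i \sim
  N\!\big(\nu_{ic} + b(\mathrm{QALY}_i - \nu_{iq}) + (1 - S_i)\Gamma,\;
  \sigma_c^2\big),$$

with $\nu_{ic}$ a covariate-adjusted arm intercept on the cost scale and
$\nu_{iq} = w^\top \mu_i$. Together with the QoL model this is a full
bivariate (QALY, Cost) normal model; we parameterise it conditionally
because that gives direct, independent priors for the slope and residual
spread and makes every update conjugate. The marginal (QALY, Cost)
covariance is recovered deterministically:
$\sigma_q^2 = w^\top \Sigma_k w$, $\mathrm{cov} = b\,\sigma_q^2$,
$\sigma_{c,\mathrm{marg}}^2 = \sigma_c^2 + b^2 \sigma_q^2$. The slope and
residual sd are shared across arms; only $\Sigma_k$ is arm-specific.

Because each missing QoL value is imputed from its bivariate conditional,
a patient's observed score still informs their missing one through
$\Sigma_k$ — the offset shifts the mean, it does not sever the
correlation.

Treatment increments are monitored as *marginal* (pattern-averaged) mean
differences: per draw, the average of $\mu_{ij}$ over patients in each arm
(including the $\Delta$ offsets for those with missing data) is
differenced between arms. Under MAR this coincides with the intercept
contrast $\eta_{j2} - \eta_{j1}$ (which is also monitored); under MNAR it
is the estimand that reacts to $\Delta$, which is the point of the
sensitivity analysis.

## Expert elicitation and pooling

Experts are asked about the QoL *level* of typical non-responders, per
arm, with a spread (interpreted as a standard deviation) and one
conditional question — their expected intervention-arm level given a
stated control-arm level — from which the cross-arm correlation is
recovered by inverting the bivariate-normal conditional mean. Implied
correlations outside $(-0.999, 0.999)$ are clipped with a warning; a
conditioning value equal to the stated location is rejected with an
instruction to re-elicit, since it leaves the correlation undefined.

A panel is aggregated by linear opinion pooling — a weighted arithmetic
mean of densities, i.e. a finite mixture of bivariate normals — with equal
weights by default and arbitrary weights retained for subgroup pools
(doctors/nurses, face-to-face/online). "Most/least certain" experts are
selected by the determinant of their covariance (generalised variance);
this criterion is a package choice, exposed as an argument, and ties break
by panel order. Elicited levels become offsets by subtracting the
observed-data arm means at the elicited timepoint; covariances are
unchanged by this location shift. The time-invariance default shares one
$\Delta_k$ per arm across timepoints; per-timepoint offsets (independent
copies of the prior) are available via `delta_time_invariant = FALSE`.

## Priors and numerical choices

* Intercepts and coefficients: $N(0, 100^2)$ — effectively flat on the
  utility scale and on the internal cost scale (costs are divided by
  1,000 for sampling stability and rescaled on output).
* QoL precision $\Sigma_k^{-1}$: Wishart with the minimum degrees of
  freedom ($J = 2$) and rate matrix $0.01\,I$ — weakly informative on the
  utility scale, where QoL variances sit around 0.01–0.1, adding the
  equivalent of well under one observation.
* Conditional cost residual sd: uniform on $(0, 100)$ thousand GBP.
* Morbidity-index submodel: the 5-level category probabilities get
  arm-specific Dirichlet(1, …, 1) priors with a categorical likelihood;
  this is the simplest covariate imputation model consistent with the
  joint structure, and missing categories are drawn from their exact
  full conditional (enumerating the five categories against the QoL and
  cost likelihoods).
* Gibbs sampler: every full conditional in this Gaussian model is
  standard — normal blocks for the regression coefficients (the QoL block
  accounts for the cost feedback through $-b\,\nu_{iq}$), Wishart for the
  precisions, truncated inverse-gamma for $\sigma_c^2$, categorical and
  Dirichlet for the covariate submodel, and normal draws for every
  imputation. No Metropolis step or step-size tuning is therefore needed;
  the sampler is pure Gibbs with data augmentation.
* Mixture prior on $\Delta$: handled by component-indicator augmentation
  with a *collapsed* update — the indicator is drawn with $\Delta$
  integrated out (closed-form Gaussian marginals per component), then
  $\Delta$ is drawn from the selected component's conditional. The naive
  alternate-conditional scheme mixes poorly across a 25-component pool;
  the collapsed update removes that coupling.
* Initialisation is diffuse: intercepts $N(\text{data mean},
  (4\,\text{data sd})^2)$, covariances at complete-case estimates, offsets
  drawn from their prior. Non-finite starting densities are re-drawn up to
  20 times. Two chains are the default; convergence requires the classic
  (rank-free) Gelman–Rubin statistic below 1.05 for every monitored
  quantity, with trace data exported for visual checks. Warmup (default
  5,000 per chain for the full-length run) is discarded; no thinning by
  default.
* Degenerate inputs: non-positive-definite $\Sigma_k$ proposals are
  impossible by construction (Wishart draws), and `log_joint()` returns
  $-\infty$ for them by contract; a positive-definiteness check with a
  *relative* tolerance accepts near-degenerate but valid expert
  covariances (tiny elicited spreads); density strips floor the kernel
  bandwidth when draws are constant; ties at INB exactly zero count as
  not cost-effective.

## The synthetic-trial generator

Real patient-level data of this kind are not freely distributable, so the
generator is a first-class module producing trials with *exactly* the
structure the model assumes: covariates first, then the missingness
pattern, then outcomes given the pattern — QoL from the pattern-specific
mean (base mean, plus $\Delta_{jk}$ for values destined to be missing),
cost conditionally on the realised QALY. Drawing the pattern first makes
the generating $\Delta$ exactly the estimand of the sensitivity analysis,
so recovery is testable. MCAR and MAR mechanisms (logistic in age) can
also be applied as post-hoc masks to a complete dataset; pattern-mixture
MNAR cannot, and `apply_missingness()` refuses it.

Defaults emulate a two-arm emergency-surgery trial of 301 twelve-month
survivors: arms of 140/161, utility-scale QoL means around 0.66–0.75 with
incremental QoL of 0.063 and 0.046 at the two timepoints, incremental
cost of −704 GBP, QoL missingness of 17–27% by arm and timepoint, cost
missingness near half, morbidity-index missingness 10–14%. These defaults
are the package's study conditions and are not tuned per analysis.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: QoL distributions are normal, not skewed
or spiked at 0/1 as real EQ-5D data are (generated utilities can exceed
1); costs are normal rather than right-skewed; missingness is independent
across endpoints given covariates, with no monotone dropout structure; and
the generator's MAR mechanism uses only modelled covariates, whereas real
missingness may track unmodelled ones (length of stay, blood pressure).

## Validation design

The test suite checks each layer against an independent route: the joint
log-density against a hand-built trivariate-normal oracle; posterior arm
means on complete data against the conjugate closed form (sample means,
within Monte Carlo error); mixture moments and the linear-pool identity
against direct component sums; the Gelman–Rubin statistic against the
reference implementation in `coda`; and the tipping-point scan against
the analytic linearity of the posterior-mean INB in a fixed offset, whose
slope is the willingness-to-pay times the duration-weighted missing
proportions of the intervention arm.

Interval calibration on MNAR data uses the Bayesian calibration design:
each replicate draws its true $\Delta$ from the sensitivity prior (centred
at $(-0.15, -0.15)$), generates a 300-patient trial, and fits the
correctly specified model. With this design 95% intervals cover the truth
95% of the time *by construction* for identified and unidentified
parameters alike, so observed coverage is a sharp correctness check. A
fixed $\Delta$ equal to the prior centre would instead make coverage of
$\Delta$ trivially 1 — in a pattern-mixture model the offset's posterior
equals its prior, since the observed-data likelihood is flat in it — which
checks nothing; the long-run prior-recovery property is tested separately.

Problem sizes in the suite (24 calibration replicates, chains of a few
thousand sweeps, trials of 300) are the package's chosen desk-scale
defaults; the full-length protocol (two chains, 50,000 kept draws) is the
`mcmc_settings()` default for real analyses.

## Limitations

Normal QoL and cost likelihoods (no Beta/Gamma variants); a single
incomplete covariate pattern is supported (the 5-level morbidity index);
no survival or decedent accounting, so the analysis targets survivors
eligible for follow-up; elicitation covers one timepoint, extended by the
time-invariance assumption rather than elicited time profiles; and
selection-model alternatives to the pattern-mixture factorisation are out
of scope.
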