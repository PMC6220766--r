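# ceamiss

Bayesian cost-effectiveness analysis (CEA) for two-arm trials with missing
data, built for health economists and trial statisticians who need to say
how robust a cost-effectiveness conclusion is when quality-of-life (QoL)
questionnaires, cost records or baseline covariates are incomplete — and
when the usual "missing at random" (MAR) assumption is doubtful.

Multiple imputation and most Bayesian CEA models assume MAR. But the
patients who fail to return an EQ-5D questionnaire are often the ones in
worse health, so the data may be missing **not** at random (MNAR), and no
amount of data can settle the question. `ceamiss` makes the departure from
MAR an explicit, expert-informed model quantity and propagates the
resulting uncertainty into the decision outputs.

## The model

For patient *i* in arm *k* (arm 1 = control), with QoL scores
QoL<sub>ij</sub> at follow-up *j* = 1, 2, aggregate cost Cost<sub>i</sub>,
and covariates (age, sex, a 5-level morbidity index):

* **QoL imputation model** — arm-specific bivariate normal,
  (QoL<sub>i1</sub>, QoL<sub>i2</sub>) ~ BVN(μ<sub>i</sub>, Σ<sub>k</sub>),
  with μ<sub>ij</sub> = η<sub>jk</sub> + β<sub>a</sub> age + β<sub>s</sub> sex
  + β<sub>h,hardman(i)</sub>.
* **Substantive model** — QALY<sub>i</sub> = ½ QoL<sub>i1</sub> + ⅜ QoL<sub>i2</sub>
  (duration-weighted), and (QALY, Cost) jointly normal, fitted through the
  conditional step Cost<sub>i</sub> | QALY<sub>i</sub> ~
  N(ν<sub>ic</sub> + b (QALY<sub>i</sub> − ν<sub>iq</sub>), σ<sub>c</sub>²),
  which links both parts into one joint posterior.
* **Pattern-mixture MNAR** — when QoL<sub>ij</sub> is unobserved
  (R<sub>ij</sub> = 0) its mean is shifted:
  μ<sub>ij</sub> += (1 − R<sub>ij</sub>) Δ<sub>jk</sub>; similarly Γ for
  missing costs. Δ is the average difference between missing and observed
  values — not identifiable from the data, so it carries a prior.
* **Expert-elicited priors** — each expert's belief about the QoL of
  typical non-responders in the two arms is a bivariate normal
  (location, spread per arm, cross-arm correlation recovered from one
  conditional question); a panel is aggregated by linear opinion pooling
  into a mixture prior, which the model converts to an offset prior by
  subtracting observed-data arm means.
* **Inference** — a Gibbs sampler with data augmentation (missing QoL,
  costs and morbidity categories drawn each sweep; a collapsed update for
  the mixture-prior component), two chains, Gelman–Rubin R̂ < 1.05.
* **Decision outputs** — incremental QoL/QALY/cost, incremental net
  benefit INB = λ·ΔQALY − ΔCost (default λ = 30,000 GBP/QALY),
  P(cost-effective) = P(INB > 0), CEAC, density strips, and tipping-point
  scans over fixed Δ.

## Worked example

```r
library(ceamiss)

trial <- generate_trial(sim_config(seed = 42))      # synthetic 301-patient trial
summarize_missingness(trial$data)

panel <- generate_expert_panel(25, seed = 43)       # stand-in expert panel
prior <- elicited_levels_to_offsets(pool_experts(panel),
                                    observed_qol_means(trial$data))

settings <- mcmc_settings(n_chains = 2, n_iter = 10000, warmup = 1000, seed = 44)
fit_mar  <- run_mcmc(build_model(model_config(), trial$data), settings)
fit_mnar <- run_mcmc(build_model(model_config(qol_missingness = "MNAR"),
                                 trial$data, prior), settings)

incremental_summaries(fit_mnar)
inb(fit_mnar); prob_cost_effective(fit_mnar)
assess_convergence(fit_mnar)
```

This prints, first, the missingness table

```
Level of missing data by treatment arm
                         arm 1      arm 2      total
Number of patients         140        161        301
QoL at timepoint 1        36 (26%)  30 (19%)    66 (22%)
QoL at timepoint 2        38 (27%)  34 (21%)    72 (24%)
Cost                      81 (58%)  77 (48%)   158 (52%)
Morbidity index           22 (16%)  22 (14%)    44 (15%)
```

and then the posterior summaries (mean and 95% equal-tailed interval):

```
MAR   inc_qaly 0.0687 ( 0.0213, 0.116)   inc_cost  657 (-1210, 2514)
      INB 1403 (-1017, 3857)   P(CE) 0.874
MNAR  inc_qaly 0.0620 (-0.0324, 0.156)   inc_cost  638 (-1260, 2470)
      INB 1222 (-2189, 4626)   P(CE) 0.756
```

Read: under MAR the intervention gains ~0.069 QALYs at a higher cost of
~£657, for a mean INB of ~£1,400 at £30,000/QALY and an 87% chance of
being cost-effective. Allowing the QoL data to be MNAR with the pooled
expert prior barely moves the point estimates but widens every interval —
the honest price of not knowing the missingness mechanism — and the
probability of cost-effectiveness drops to 0.76. Both fits pass the
R̂ < 1.05 convergence check.

A command-line wrapper covers the same workflow
(`exec/ceamiss simulate | pool | fit | report`).

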