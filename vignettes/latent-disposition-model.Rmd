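---
title: "A latent health-state model for emergency-department disposition decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latent health-state model for emergency-department disposition decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edlatent)
```

## The problem

When an older adult arrives at an emergency department (ED) with a
"gray-area" presentation — falls, weakness, syncope, urinary tract
infection, pneumonia, or cellulitis — there is often no clear standard for
whether to admit them to the hospital or discharge them. Comparing outcomes
of admitted and discharged patients directly is misleading because of
*confounding by indication*: sicker patients are preferentially admitted,
and their severity also drives revisits, readmission and death. Much of
that severity is visible to the treating clinician but not recorded in
discrete EHR fields.

`edlatent` estimates the average effect of admission versus discharge on
nine binary outcomes (ED revisit, hospital readmission, mortality within 3,
9 and 30 days of final discharge) while adjusting for *both* measured
covariates and an unmeasured severity component, by treating severity as a
latent variable for which triage acuity and vital signs are noisy proxies.

## The model

Write \(X_i\) for the encoded baseline covariates of visit \(i\) (age, sex,
insurance class, diabetes, congestive heart failure, hypertension, HCC
comorbidity score), \(W_i\) for the proxies (an ESI acuity = 2 indicator
and four standardized vitals), \(A_i \in \{0,1\}\) for admission,
\(T_i > 0\) for the treatment time (hours from ED rooming to the
disposition decision), and \(Y_{ik}\) for outcome \(k\). The latent health
state \(H_i \in \{0,1\}\) (1 = adverse) ties the components together:

* **Latent prior** — logistic regression:
  \(P(H_i = 1 \mid X_i) = \operatorname{expit}(\eta_0 + \eta' X_i)\).
* **Proxy measurement models** — each continuous proxy
  \(W_{ij} \sim N(\alpha_j + \lambda_j H_i + \kappa_j' X_i, \sigma_j^2)\);
  the binary acuity indicator follows a logistic model with a latent
  effect. The \(\lambda_j\) make the proxies informative about \(H\).
* **Admission process (threshold regression)** — a latent evidence process
  for the disposition: a unit-diffusion Wiener process starts at
  \(w_0 a\) between a discharge boundary at 0 and an admit boundary at
  \(a > 0\), with drift
  \(\mu_i = \delta_0 + \delta_H H_i + \delta_X' X_i + \delta_W' W_i\).
  The first boundary crossed gives the decision and the crossing time the
  treatment time, so the model explains the *pair* \((A_i, T_i)\). The
  defective first-passage density at each boundary is evaluated by the
  standard dual series (image expansion at small scaled time,
  eigenfunction expansion at large scaled time), with terms accumulated
  until they fall below `1e-9` and the whole computation carried out in
  the log domain. Diffusion is fixed at 1 and the boundary and start point
  are covariate-free, which is the minimal identifiable parameterization
  linking drift to latent health, baseline and proxies.
* **Outcome models** — identity-link Bernoulli:
  \(P(Y_{ik} = 1 \mid H_i, A_i) = \beta_{k0} + \beta_{kH} H_i +
  \beta_{kA} A_i + \beta_{kHA} H_i A_i\), clamped to
  \([\varepsilon, 1-\varepsilon]\) with \(\varepsilon = 10^{-6}\) so the
  likelihood stays valid while the parameters remain on the
  risk-difference scale. The admission main effect and the
  latent-admission interaction are included so the counterfactual contrast
  is well defined and subgroup heterogeneity can be expressed.

The observed-data likelihood marginalizes \(H_i\) over its two states; the
model is a two-component finite mixture and is fitted by
expectation-maximization. The E-step responsibility
\(\gamma_i = P(H_i = 1 \mid \text{all observed data for } i)\) has a closed
form; the M-step is exact for every component: weighted logistic fits for
the prior and the acuity proxy, weighted least squares for the continuous
proxies, quasi-Newton maximization (warm-started, with a closed-form drift
gradient) for the threshold component, and weighted cell means — the exact
constrained maximizer under the identity link — for the outcomes. A
component whose refit would lower its expected log-likelihood is kept at
its previous value, so the observed log-likelihood trace is nondecreasing
by construction.

Mixture label swapping (\(H \leftrightarrow 1-H\)) leaves the likelihood
unchanged; fits are canonicalized so the latent effect on the first
continuous proxy (temperature) is nonnegative, i.e. the adverse state is
the febrile/tachycardic one.

### Which outcomes enter the likelihood

By default only the three 30-day indicators enter the joint likelihood.
The 3- and 9-day indicators are deterministic truncations of the same
events (an event within 3 days is an event within 30), so treating all
nine as conditionally independent Bernoullis would misspecify the joint
distribution and distort the posterior weights. Models for the short
windows are instead estimated from the final responsibilities, which is
consistent because the day of an event carries no information about the
latent state beyond the event indicator itself. A config switch
(`em_control(likelihood_outcomes = ...)`) changes the included set. A
side effect is that the delta-method standard errors for 3- and 9-day
effects do not propagate the extra binomial noise of the day-of-event
draw; bootstrap standard errors are the alternative when those windows are
of primary interest.

## Counterfactual effects

With fitted parameters \(\hat\theta\) and final responsibilities
\(\gamma_i\), the predicted potential outcome under forced admission
status \(a\) is
\(\gamma_i\, p_k(1, a) + (1-\gamma_i)\, p_k(0, a)\), holding everything
else at its observed value. The average treatment effect (risk difference)
is the mean over visits of the difference between the two forced
predictions, which reduces to
\(\hat\beta_{kA} + \hat\beta_{kHA}\,\overline{\gamma}\); subgroup effects
average over the selected visits only, so size-weighted subgroup effects
reproduce the overall effect exactly. Integrating over the *posterior*
(not the prior) is deliberate: the counterfactual holds each visit's
observed proxies and admission data fixed, so the latent state should be
conditioned on them.

Standard errors propagate a parameter covariance through a
central-difference gradient of the risk difference (delta method); Wald
intervals and 2-tailed tests at \(\alpha = 0.05\) follow. No
multiple-testing adjustment is applied anywhere; intervals and p-values
are nominal.

The parameter covariance is the inverse of the observed information
estimated from the **outer product of per-visit score vectors**, with
scores obtained by central differences of the per-visit log-likelihood.
For this ~100-parameter model the score-based estimate costs \(2p\)
likelihood sweeps instead of the \(O(p^2)\) sweeps of a full numerical
Hessian, and simulation checks in the test suite show ~94% pooled coverage
of 95% intervals at \(n = 5000\). `em_control(cov_method = "hessian")`
switches to the numerically differentiated Hessian. When the information
matrix is not positive definite — which happens when a covariate is almost
constant, e.g. a 0.1%-prevalence insurance class — eigenvalues are clipped
at a small positive floor, which inflates the affected standard errors
and is flagged in the fit.

## Comparator estimators

Three estimators that ignore the latent state are included for the same
risk differences: the unadjusted two-proportion contrast; Hájek
(normalized) inverse probability weighting with a logistic propensity on
baseline + proxies and bootstrap standard errors; and parametric
g-computation (a logistic outcome model on admission, baseline and
proxies, standardized over the empirical covariate distribution). Under
randomized disposition all four estimators agree; under confounding
through the latent state the comparators are biased while the latent model
— given informative proxies — is not. The test suite reproduces both
regimes as simulation properties.

## The synthetic cohort generator

No patient-level data ship with the package. The generator draws cohorts
from exactly the structure the model assumes, with defaults chosen once to
emulate an older-adult gray-area ED population: mean age 79 (SD 9,
truncated at 65), 58.5% female, 92% Medicare, comorbidity prevalences near
21%/12%/58% (diabetes/CHF/hypertension), a gamma HCC score with mean 1.65,
presentation shares of 44/16/13/13/8/6% (falls/weakness/syncope/UTI/
pneumonia/cellulitis), vitals centered at their usual clinical values, and
an admitted fraction near 39%. The latent state moves temperature, heart
rate, respiration rate up and blood pressure down by clinically modest
amounts (0.4–0.8 proxy SDs), raises the odds of ESI 2, and adds 1.3 units
of admission drift; 30-day outcome probabilities and admission effects
(−6.4, +5.8 and +1.0 percentage points for revisit, readmission,
mortality) are of the size reported for comparable cohorts. Each outcome
family is generated as a single 30-day Bernoulli event whose day (if it
occurs) is uniform on (0, 30], so the 3/9/30-day indicators nest by
construction. Ground truth (latent states, drifts, per-visit admission
effects and true average treatment effects) is recorded before missingness
is injected.

Missingness is completely at random, matching what median/mode imputation
assumes. Screening fields (troponin, pulse oximetry, systolic blood
pressure, diagnosis flags, visit dates) are generated with small
abnormality rates so the cohort filters have realistic work to do.

What the generator does *not* emulate: informative missingness, measurement
drift over calendar time, within-patient correlation across repeat visits,
competing risks (death censoring of later revisits is available behind a
flag, default off), and any deviation between the fitted model family and
the data-generating process. Passing recovery tests on these cohorts
therefore demonstrates internal correctness of the estimator chain, not
robustness to real-EHR misspecification.

## Cohort definition and preprocessing

Filters retain visits with: a recorded disposition of admission or
discharge to home/SNF/IRF (transfers, eloped and against-medical-advice
excluded; SNF/IRF discharges are analyzed as discharges), ESI acuity 2–3,
a visit at least 45 days before the end of the sample period, troponin
absent or ≤ 0.10 ng/mL, no recorded systolic BP < 80 mmHg, respiration
rate > 30/min, pulse oximetry < 88% or heart rate > 120/min, no
stroke/MI/femur-fracture flag, and no cellulitis-with-fever
(temperature > 100.3 °F). All cutoffs are strict as written, so boundary
values are retained; a missing screening vital never excludes (absence of
evidence of an abnormality). Each excluded visit is counted under the
first failing rule in a fixed order (disposition, acuity, 45-day tail,
troponin, vitals, diagnosis flags, cellulitis/fever) so reports are
reproducible. Remaining choices: "within N days" is boundary-inclusive;
imputation (median for continuous, most frequent category with
lexicographic tie-break for categorical) runs after filtering;
standardization uses the post-imputation sample mean and SD (denominator
n − 1) and is applied before estimation, with the scaling retained for
inverse transforms.

## Numerical choices

* FPT series switch at scaled time \(\tau = t/a^2 = 0.15\); both
  representations agree to ~1e-12 on a wide overlap band.
* Density evaluations are floored at a large negative log value instead of
  \(-\infty\) so zero-weight terms cannot produce NaNs and optimizers see
  a finite penalty.
* The generator's first-passage simulation uses an Euler step of
  \(10^{-4} a^2\) *plus* a Brownian-bridge crossing check within every
  step; without the bridge correction the crossing-miss bias
  (\(O(\sqrt{dt})\)) would exceed Monte-Carlo error at the tested path
  counts.
* EM defaults: 10 restarts (the first from a deterministic principal
  component split of the continuous proxies, the rest perturbed), at most
  500 iterations, relative log-likelihood tolerance 1e-8. The examples and
  tests use 1–2 restarts and 20–100 iterations, which this model reaches
  comfortably at the simulated sizes (fits at n = 5000 typically converge
  in 40–70 iterations).
* Logistic linear predictors are capped at ±30, which keeps the
  likelihood finite under complete separation and flags it.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_visits = 5000, seed = 1)
cohort <- generate_cohort(cfg)
data <- inject_missingness(cohort$data, cfg$missingness_rates, seed = 2)
prep <- preprocess_cohort(data, cfg$sample_period[2])
fit <- fit_em(prep$design, em_control(n_restarts = 2, max_iter = 100,
                                      rel_tol = 1e-7, seed = 3))
estimate_ate(fit, prep$design, "y_readmission_30")
unadjusted_rd(prep$design, "y_readmission_30")
```

The same pipeline, end to end with tables and a manifest, is
`run_pipeline(pipeline_config(...))`; `scripts/acceptance.R` runs it
against ground truth and writes the headline numbers as JSON.

## Known limitations

* Binary latent health. The state could plausibly be ordinal or
  continuous; the logistic-prior formulation adopted here is the smallest
  model consistent with the component structure, and the generator config
  leaves room for a K-state extension.
* Identification rests on proxy informativeness (\(\lambda \ne 0\)) and on
  the two standard assumptions: potential outcomes independent of the
  decision given latent health and baseline, and independence across
  visits. None of these are testable from the data alone.
* Subgroup intervals propagate parameter uncertainty only, not the
  sampling variability of subgroup membership.
* The threshold component is one member of the threshold-regression
  family (Wiener, two boundaries, covariate drift). It is isolated behind
  `threshold_params`/`admission_loglik` so an alternative first-hitting
  process could be swapped in.
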