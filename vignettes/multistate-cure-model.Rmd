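---
title: "A Bayesian multistate cure model for oropharyngeal cancer prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian multistate cure model for oropharyngeal cancer prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curemsm)
```

## The model

After primary treatment for oropharyngeal squamous cell carcinoma (OPSCC),
a patient is assumed to occupy one of three initial states, fixed at
baseline but possibly unobserved:

* **persistent disease (state 6)** — observable cancer at or around the
  posttreatment evaluation;
* **noncured (state 1)** — complete response, but the cancer will recur if
  the patient lives long enough;
* **cured (state 2)** — complete response and no recurrence, ever.

Two logistic regressions govern the initial state: C1 models
$P(\text{persistent})$ and C2 models $P(\text{noncured} \mid
\text{nonpersistent})$, each on baseline covariates. Event transitions
follow proportional-hazards models with time in months:

* C3: noncured $\to$ locoregional recurrence (LRR),
* C4: noncured $\to$ distant metastasis (DM),
* C5: noncured or cured $\to$ death without prior recurrence,
* C6: persistent $\to$ death (no covariates — these deaths occur quickly),
* C7 / C8: death after LRR / DM, on a **clock reset** at recurrence
  (semi-Markov: the hazard argument is months since entering the
  recurrence state).

C5–C8 use Weibull baselines, $h_0(t) = (k/\lambda)(t/\lambda)^{k-1}$.
C3 and C4 use **piecewise Weibull** baselines with a change point at 6
months: each segment is a Weibull hazard evaluated on the global time
axis, and the cumulative hazard is the sum of segment integrals, so
$H_0$ is continuous while $h_0$ may jump at 6 months. (Whether the second
segment should instead restart its time origin at the change point is a
genuinely open choice; we adopt the continuous-cumulative-hazard
convention because it keeps survival functions continuous and inverts in
closed form.)

Covariates are dummy-coded against the reference patient: male, no ACE27
comorbidity, never smoker, no anemia (hemoglobin $\ge$ 13/12 g/dL for
men/women, strict), p16-positive, cT1, cN0/cN1 merged, no radiologic
extracapsular extension (rECE; equivocal reads are coded negative at
ingestion). Age and log metabolic tumor volume (logMTV, log mL) are
z-scored with constants stored alongside the parameters so predictions on
new data reproduce exactly. Each component uses a covariate subset,
configured in `component_specs()` rather than hard-coded; the defaults
follow the covariates reported per component for this disease, and a
second formulation adds the imaging markers (logMTV, rECE) to C2–C4.

### Likelihood

For a patient with covariates $x$, the complete-data likelihood given an
assigned initial state multiplies the initial-state probability by the
transition terms: persistent patients contribute a C6 density or survival;
cured patients a C5 density or survival; noncured patients the
competing-risk factor $e^{-(H_3+H_4+H_5)(t_1)}$ with the cause-specific
hazard at the first event, and — after a recurrence — a C7/C8 density or
survival on the reset clock. Nonpersistent, recurrence-free patients have
latent state in $\{1, 2\}$ regardless of follow-up length; the
observed-data likelihood sums both branches. The study's descriptive
72-month "cured" label is carried in the data (`cured_label`) but never
enters the likelihood.

## Synthetic cohorts

No patient-level data are distributable, so `generate_cohort()` emulates
the statistical structure the analysis assumes. Covariate marginals follow
the training cohort (85.1% male, median age 58, smoking
33.0/34.5/31.9% never/former/current, 82.8% p16-positive among known,
median MTV 13.6 mL), independently by default — the source reports only
marginals — with an optional smoking-by-p16 association. Missingness is
masked MCAR at the reported "unknown" fractions (p16 38.9%, ACE27 26.5%,
cN 12.7%, anemia 14.0%; MTV and rECE jointly at 67.1%, since both come
from the same scan). Event times are drawn by exact cumulative-hazard
inversion, with the 6-month split handled analytically (no rejection
sampling). Censoring is administrative: uniform accrual over 163 months
with a data lock 194 months after accrual opened, mimicking enrolment over
many years with a fixed analysis date.

The observation scheme applies the study's labelling conventions: a
recurrence at or before 3 months is recorded as persistent disease (the
~12-week evaluation window), as is a death within 6 months with under 3
months of recurrence follow-up; both windows are configurable.

`reference_params()` is the fixed generating truth. Its signs follow the
reported association pattern (e.g. persistent disease more likely with
severe comorbidity, cT4 and p16-negativity; metastasis hazard increasing
in cN; the rECE odds ratio on noncure is 3.67 and its DM hazard ratio
5.11), and its baselines were calibrated once so that generated cohorts
reproduce the training cohort's outcome frequencies: 5.4% persistent
(target 5.6%), 24% observed recurrence (22.0%), 38% deaths (32.4%). One
known deviation: ~45% of synthetic patients reach 72 recurrence-free
months versus 22.1% in the real cohort, because uniform accrual gives
longer median potential follow-up than the real accrual pattern; the label
is descriptive and unused by the model.

What passing tests on these cohorts do **not** show: robustness to
covariate dependence structures, informative censoring, interval-censored
recurrence detection, measurement error in imaging markers, or
second-primary adjudication — none of which the generator emulates.

## Estimation

`run_mcmc()` is a Metropolis-within-Gibbs sampler (defaults 25 000
iterations, 10 000 burn-in):

1. **Imputation.** Missing covariates are redrawn inside the chain by
   chained equations (every 10th iteration by default): logistic models
   for binary covariates, multinomial for categorical, linear for
   continuous, each conditioned on the other current covariate values
   plus an any-event indicator and log follow-up time. Ten completed data
   sets are retained for prediction-time averaging. Fits are refreshed
   rather than redrawn every iteration because the conditional-model
   refits dominate runtime while the completed tables change slowly.
2. **Latent states.** Each ambiguous record's state is drawn from its
   exact two-branch full conditional, $P(\text{noncured}) \propto
   q\,e^{-(H_3+H_4)(t)}$ vs $(1-q)$ — the C5 factor is common and cancels.
3. **Parameters.** Each parameter gets an adaptive random-walk Metropolis
   update (Robbins–Monro adaptation toward 44% acceptance, during burn-in
   only, so the retained chain is exactly Markov). Baseline shapes and
   scales are sampled on the log scale.

One deliberate algorithmic choice: the C2/C3/C4 updates target the
**collapsed** likelihood, with the latent state summed out in closed form,
rather than the augmented complete-data factors. Both are exact, but
augmented updates mix poorly here — the labels carry spurious certainty,
and split-chain R-hat stayed near 1.5–1.8 after 5000 iterations, versus
~1.0 collapsed. Given the states, all other components factorize, so each
update touches only its own likelihood term.

Priors are weakly informative normals — N(0, 2.5²) on coefficients and
intercepts, N(0, 1²) on log shapes, N(3, 3²) on log scales (scales in
months; e³ ≈ 20 months) — truncated by order restrictions: by default the
C4 (metastasis) log hazard ratios must be nondecreasing across cN
categories starting from the reference at zero, enforced by rejecting
violating proposals, which is exactly a truncated prior. Initial values
come from component-wise fits (logistic fits for C1/C2 with latent states
at their most probable values, intercept-only Weibull fits for baselines)
with moment-based fallbacks, so chains start near the mode.

### What recovery experiments can and cannot achieve

With latent cure status, parts of C2 are intrinsically weakly identified:
a higher-cT patient with long recurrence-free follow-up is consistent both
with "likely cured" and with "noncured but slow to recur", because cT
raises the noncure odds (C2) while lowering the LRR hazard (C3). At
n = 2000 the posterior for the C2 cT coefficients is correspondingly wide
(sd ≈ 0.5–0.9), and even the oracle-state MLE misses some coefficients by
more than 0.15 on the log scale. Recovery tests therefore check posterior
means loosely and interval calibration strictly: across replicates
simulated with a null anemia effect in C2, the 95% credible interval
covers zero at close to the nominal rate.

## Prediction

`occupancy_curve()` computes state-occupancy probabilities over eight fine
states (event-free alive; alive after LRR; alive after DM; alive
persistent; dead after LRR-first; dead after DM-first; dead persistent;
dead without recurrence), mixing over the initial states. The noncured
branch requires convolution integrals on the reset clock,
$\int_0^t h_k(u)\, e^{-(H_3+H_4+H_5)(u)}\, S_{k'}(t-u)\, du$, evaluated by
composite Simpson quadrature on a 0.1-month grid with the 6-month change
point as a mandatory knot. Two numerical safeguards matter:

* the leading subinterval $[0, 0.1]$ is integrated via the cumulative
  hazard with the smooth factors at its midpoint, because Weibull hazards
  with shape < 1 are singular at zero and naive quadrature there is
  catastrophically wrong;
* the five cause-specific paths of the noncured branch are renormalized to
  partition $1 - e^{-(H_3+H_4+H_5)(t)}$ exactly — quadrature fixes the
  split, the total is analytic — so occupancy sums to one at machine
  precision, and halving the step changes no probability by more than
  1e-4.

The four reporting categories are: (1) no event, (2) DM first (alive or
dead), (3) LRR first **or persistent disease** (alive or dead; persistent
patients occupy this category from time zero), (4) death without
recurrence or persistence. Classification is by first event; later
transitions (e.g. metastasis after LRR) do not reassign the category.
Overall survival is one minus total dead occupancy; event-free survival is
the event-free-alive occupancy, with persistence counting as an event at
time zero.

Prediction uses the posterior-mean plug-in. For patients with missing
covariates, `predict_with_missing()` averages curves over (default) 10
draws from imputation models fit to a completed reference cohort — outcome
summaries are excluded from those models since predictions precede
outcomes. Averaging convex combinations preserves the sum-to-one
constraint. `patient_report()` tabulates the four categories monthly
through 60 months with 5-year OS/EFS scalars.

## Validation

* **Time-dependent AUC** (`time_dependent_auc`): cumulative-case /
  dynamic-control at the horizon with inverse-probability-of-censoring
  weights from a marginal Kaplan–Meier estimate of the censoring
  distribution (the estimator is recorded in the output metadata; it
  reduces to Mann–Whitney without censoring).
* **Concordance** (`concordance_index`): Harrell's C over usable pairs,
  risk ties counted one half, tied times excluded; cross-checked against
  `survival::concordance` in the tests.
* **Calibration** (`calibration_by_strata`): mean predicted category
  probabilities versus Aalen–Johansen cumulative incidence of the
  competing first events (via `survival::survfit` multistate) and the
  Kaplan–Meier event-free estimate, within strata such as cT or p16, with
  the persistent fraction entering category 3 at time zero.
* **Cox–Snell** (`cox_snell_diagnostics`): residuals are the model-implied
  marginal cumulative hazard of death at each observed time (marginal over
  the latent state, not conditional on augmentation draws). Under a
  correct model the censored residuals are unit-exponential; the check
  requires the residuals' KM curve to sit inside pointwise 95% Greenwood
  bands of $e^{-r}$ at the residual deciles (at least 90% of points), and
  reports the origin-constrained slope of the residual cumulative hazard,
  which is 1 under a correct model and moves far from 1 when, e.g., all
  death hazards are halved.

## Problem sizes and numerical choices

The shipped tests exercise: conservation over 100 random configurations on
a 0–120-month grid; analytic-vs-simulation agreement within ±0.01 over 20
configurations of 100 000 trajectories; a recovery fit at n = 2000 with
5000 iterations plus 20 interval-coverage replicates at n = 600;
self-calibration within ±0.03 on an independent n = 10 000 cohort; exact
pairwise-enumeration oracles for AUC and concordance; a Cox–Snell
correct-vs-misspecified contrast at n = 3000; and bitwise reproducibility
of cohorts, draws and reports under fixed seeds. Degenerate inputs are
handled explicitly: hazards at t = 0 are floored at 1e-10 inside event
log-densities, empty covariate subsets give zero-column designs, and
zero-length risk sets contribute zero log-likelihood.

## Limitations

Treatment is deliberately absent — predictions are treatment-independent
by design, so the model cannot compare modalities. The cohort generator's
independence and MCAR defaults are idealizations. The piecewise baseline
is limited to one fixed change point; no splines or time-varying
covariates. Imputation draws use fitted conditional parameters rather than
posterior draws of those parameters, a pragmatic approximation standard in
chained-equations practice but slightly understating imputation
uncertainty.
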