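---
title: "Methods: a progressive multistate model for diabetes complications from panel-observed EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progressive multistate modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmpath)
```

## The model and its assumptions

`dmpath` models the accumulation of diabetes complications as a
continuous-time Markov chain on five ordered states: complication-free
diabetes (`DM`), first microvascular complication (`Micro`), first
macrovascular complication (`Macro`), both types (`Both`), and `Death`.
The chain is *progressive*: transitions only move forward
(DM→Micro, DM→Macro, Micro→Both, Macro→Both, and every living
state→Death), there is no recovery, and a direct DM→Both jump is
disallowed — a patient acquires complications one type at a time, so an
apparent DM→Both change between two visits is explained by the model as
two jumps through an unobserved intermediate state.

The working assumptions, and what they buy:

* **Markov**: the future depends on the current state only. This is
  what lets intermittently observed data be handled through transition
  probability matrices.
* **Time homogeneity**: intensities are constant in time (the clock is
  years since the index visit). Sojourn times are therefore
  exponential. This keeps P(t) = exp(tQ) a matrix exponential of a
  single generator.
* **Proportional intensities**: covariates act multiplicatively,
  `q_rs(z) = q0_rs * exp(beta' z)`, with possibly different covariate
  sets per transition. `exp(beta)` is reported as a hazard ratio.
* **Non-informative observation**: visit times carry no information
  about the state process. The synthetic generator obeys this by
  construction; for real clinic data it is an approximation (sick
  patients visit more), and its violation biases any panel-likelihood
  analysis, not just this one.

## Likelihood

Per patient, with records ordered in time, each consecutive pair
(state r at t, next record at t+Δ) contributes:

| next record | contribution |
|---|---|
| panel observation of state s | `P[r,s](Δ)` |
| exact death date | `Σ_k P[r,k](Δ) · q[k,Death]` |
| censored, state in set S | `Σ_{s∈S} P[r,s](Δ)` |

The exact-death term is the standard density for an exactly observed
absorbing transition from an unknown intermediate state. State-level
censoring arises at the end of follow-up: the patient's state is
unknown but confined to the current state and its forward-reachable
non-death states. An observed pair that is impossible under the
progressive structure has probability zero; `panel_loglik()` then
returns `-Inf`, and `msm_fit()` refuses such data with an explicit
error instead of silently failing to converge.

## Numerical strategy

With states topologically ordered the generator is upper triangular,
so its eigenvalues are its diagonal entries and its eigenvectors come
from back substitution. The compiled likelihood exploits this: one
decomposition per covariate profile, then each interval's P entries are
25-term spectral sums. Gradients use the spectral Fréchet-derivative
identity dP = V (G ∘ W) V⁻¹ with `G = V⁻¹ (dQ) V`; because dQ for a
single parameter has rank one, the per-interval cost is independent of
the number of covariates per transition. Two guards matter:

* **Near-coincident eigenvalues** make the eigenbasis ill-conditioned.
  The kernel separates eigenvalues closer than `1e-8·(1+max|λ|)` by a
  deterministic nudge — equivalent to evaluating the likelihood at a
  generator perturbed in its eighth digit, far below statistical
  resolution. The divided-difference matrix W uses the confluent limit
  `t·e^{λt}` when a gap is below `1e-7`.
* The public `transition_probability()` does **not** use this path: it
  calls `Matrix::expm` (scaling and squaring), accurate to ~1e-13 on
  these small matrices, and the test suite cross-checks the compiled
  spectral path against both `Matrix::expm` and independent phase-type
  closed forms (path sums with partial-fraction coefficients) to 1e-10.

Fitting maximises over log intensities (positivity for free) with BFGS
and analytic gradients; starting values are crude occurrence/exposure
rates clamped to [1e-4, 2] per person-year. `msm_fit(starts = k)`
optionally restarts from jittered values (sd 0.25 on the log scale);
the default is a single start because the profiled log-likelihood of
this progressive model has been well-behaved in every simulation we
ran, while `run_pipeline()` uses three starts as cheap insurance on
messier real-data shapes. The covariance is the inverse observed
information via a finite-difference Hessian of the analytic gradient;
a singular information matrix flags the fit as non-converged and falls
back to a pseudo-inverse, which mirrors what happens on transitions
with too few observed events (their log-intensities drift to -∞ with
enormous standard errors, and screening treats their covariates as
non-significant).

Transitions never observed in the data are still in the model; their
estimates are vacuous and their reported intervals huge, which is the
honest answer. `pmatrix_ci()` draws from the asymptotic normal of the
MLE and clamps each draw to ±30 on the log scale — beyond that the
implied probabilities are saturated at 0/1 anyway and the matrix
exponential would overflow.

## Calibrating death intensities to a printed probability column

`calibrate_death_intensities()` solves a small inverse problem used
throughout the tests: given the four forward intensities and a target
one-year death probability per living state, find the four death
intensities such that exp(Q) reproduces the death column. Solved by
1-D root finding (`uniroot`, tolerance 1e-13) in reverse topological
order — `Both→Death` first (closed form `-log(1-p)`), then the `Micro`
and `Macro` rows, then `DM` — because each row's death-column entry
depends only on its own death rate and on later rows.

## The synthetic-data generator

`sim_config()` + `simulate_panel_cohort()` (panel records directly) and
`generate_cohort()` (full EHR-style tables) generate cohorts with known
truth. Defaults are chosen to emulate a primary-care diabetes cohort:

| parameter | default | why |
|---|---|---|
| baseline intensities | 0.1334 (DM→Micro), 0.0508 (DM→Macro), 0.0395 (Micro→Both), 0.0784 (Macro→Both) /person-year; death rates calibrated to one-year death probabilities 0.4%, 0.2%, 0.3%, 1.3% | crude five-state intensities of a large published diabetes cohort |
| sex, diabetes type, smoking | 56.2% female, 93.1% type 2, 42.8% ever-smoker | published cohort marginals |
| age | Normal(54.7, 14.1) | published cohort mean (sd) |
| visit process | homogeneous Poisson, 2 ambulatory visits/person-year, plus an index visit at 0 | roughly semi-annual primary-care contact; the visit frequency of the motivating study is not published, so this is a calibration choice |
| follow-up | per-patient Uniform(2, 7) years | staggered accrual over a five-year window followed two further years; median 4.5 y, matching published median follow-up of ~4.7 y |
| missingness | labs 15–40%, vitals 1–5%, ADI 7.4%; MCAR by default, optional MAR with logistic dependence on age | published baseline missingness ranges |

The EHR rendering: every patient gets a diabetes code at index, a prior
*hospital* visit eight months before index (so the prior-patient rule
passes without creating an earlier ambulatory index), an HbA1c lab at
every visit, and complication codes for the cumulative true state at
every follow-up visit — a diagnosis, once made, is re-coded at each
subsequent visit, which is what lets each visit be read as a panel
observation of the current state. Deaths are exact dates. Transition
times are interval-censored by construction because codes appear at the
first visit after the true jump.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real EHR data: state-dependent visit
frequency, coding error and code omission (every true state is coded,
perfectly, at every visit), clinically structured lab trajectories
(labs are stationary noise around a marginal), loss to follow-up other
than end-of-study censoring, and correlation between covariates and
visit behaviour. The biological CKD rule is exercised by hand-built
fixtures rather than by the generator (its default labs avoid the
`egfr` analyte so that code-based truth and lab-based ascertainment
cannot silently disagree).

## Cohort construction conventions

The exclusion cascade applies, in order: (1) diabetes code required;
(2) age ≥ 18 at index; (3) no complication/related/procedure code
before the study period; (4) an ambulatory follow-up visit after index;
(5) an HbA1c at index or follow-up (read as: absent at *all* visits →
exclude); (6) not a first-ever diabetes code at index without a prior
visit in either setting ≥ 6 months (183 days) earlier; (7) first micro-
and macrovascular complications not coded on the same date. The cascade
order follows the narrative order in which the criteria are usually
stated; counts are emitted as a flowchart-style audit table, and
`included + Σ excluded` always equals the number of patients entering.

Loss to follow-up is not inferred from visit gaps: without an
operational definition of a "gap" there is no principled threshold, and
misclassifying a slow returner as lost would bias the censoring sets.
Follow-up ends at death or at the administrative study end; users who
do have an operational definition can truncate the visit table before
building observations.

Times are continuous years at day resolution, `(date − index)/365.25`.
Age is floored to whole years at index. The final panel visit is the
last known-state observation; a state-level censoring record is emitted
at the end of follow-up only when it falls after the last visit.

Same-date first micro+macro pairs (order undeterminable) are excluded by
default. The sensitivity modes keep them: `all_micro` (`all_macro`)
records the assigned type at the tie visit and `Both` from the next
visit on. Recording the tie visit as `Both` directly would make the two
modes numerically identical (the likelihood would route the apparent
DM→Both jump through an intermediate state on its own), so the
assigned-type convention is what makes the sensitivity analysis a real
comparison. A same-date pair occurring *later* in follow-up, when the
patient already has one complication, is just a legal move to `Both`.

## Preprocessing

Baseline missingness is imputed by chained equations written against
base R fitters: linear regression with residual-noise draws for
continuous variables, logistic regression for binary, multinomial
(`nnet::multinom`) for categorical. Missing cells are initialized from
observed marginals; ten cycles are run (the stopping rule is a fixed
cycle count, as chained-equation convergence diagnostics are out of
scope); `m = 10` completed sets are produced and the selected set
minimises Σ over imputed variables of |mean_imputed − mean_observed| /
sd_observed, with per-level absolute proportion differences for
categorical variables. The standardised scale is a design choice (an
unstandardised sum would let large-scale variables dominate); draws
include residual noise because plug-in means understate variance.
Observed cells are never altered, and imputation is seeded. Rubin's
pooling across the m sets is deliberately not provided — the workflow
selects a single completed set and fits once.

Follow-up values use last observation carried forward; leading missing
values are left for baseline imputation. ADI deciles (1 = least, 10 =
most disadvantaged) are clustered into five categories of two with
"1-2" as the reference.

## Model building

`screen_covariates()` iterates: fit, drop per transition every
covariate whose Wald test has p ≥ α (default 0.05; a categorical
covariate is dropped only when *all* its levels are non-significant;
unidentified coefficients count as non-significant), refit; stop when
nothing was dropped or the AIC change is small (|ΔAIC| < 2) and no
longer decreasing. All non-significant covariates are dropped
simultaneously per iteration; a one-at-a-time mode exists behind a
flag. The α = 0.05 threshold is configurable — judging significance by
whether the Wald CI excludes 1 would be equivalent.

`fit_without_death()` removes the death transitions and converts each
exact death record into state-level censoring over the states reachable
from the last known living state; comparing its estimates with the full
model's checks robustness of the complication-transition effects to
mortality handling. `lrt()` performs the likelihood-ratio test between
nested fits.

## Prevalence diagnostics

`prevalence_table()` compares observed state prevalence with the
model-expected prevalence (the fitted P(0→t) row from `DM`, averaged
over the patients still under observation at t, at their own
covariates). Risk-set conventions: death is absorbing and persists;
censored patients leave both denominators after their censoring time.

The observed state between visits needs an interpolation convention.
Pure carry-forward (state of the most recent visit) dates every
transition at the *end* of its censoring interval; at two visits per
year that lags the true process by ~3 months on average and inflates
the DM curve by 5–7 percentage points — a bias that no sample size
removes and that would be misread as model misfit. The default is
therefore **midpoint** interpolation: a state change between
consecutive visits is dated at the interval midpoint, the conditional
mean of the transition time under within-interval uniformity, which
removes the first-order bias; carry-forward remains available via
`interpolation = "carry"`. On well-specified simulated cohorts of
5,000 patients the midpoint convention keeps max |observed − expected|
below 0.03 in every state over a 0–5-year grid.

## Problem sizes in the test suite

The simulation-based tests use cohorts of 500–5,000 patients at two
visits per person-year: 2,000 patients for intensity and hazard-ratio
recovery (50 replicates for interval coverage), 500 for the 200-replicate
likelihood-ratio size check, 2,000 × 50 replicates for screening, and
5,000 for the prevalence calibration check. These sizes put Monte-Carlo
error comfortably inside the asserted tolerances while keeping the
default suite in the tens of minutes on one core.

## Known limitations

* Time-homogeneous intensities and exponential sojourns; no
  semi-Markov or time-inhomogeneous extensions.
* No misclassification layer: an observed state is taken at face value
  (hidden-Markov extensions are out of scope).
* Covariates are baseline-fixed by default; time-varying covariates
  are supported by giving the covariate table a `time` column
  (carry-forward to each interval's left endpoint), but predictions
  and prevalence diagnostics then use the baseline profile.
* The non-informative-visit assumption is untestable from panel data
  alone.
* Wald intervals and tests throughout; no multiple-testing correction
  in screening, which is a descriptive model-building device rather
  than confirmatory inference.
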