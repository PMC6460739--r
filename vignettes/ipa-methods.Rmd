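---
title: "Methods: the index of prediction accuracy and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the index of prediction accuracy and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipascore)
```

## The measure

A risk prediction model assigns each subject a probability $R_i$ of an
event. The Brier score $\frac1n\sum_i (Y_i - R_i)^2$ penalises both poor
ranking (discrimination) and systematically wrong risk levels
(calibration), but its raw value is hard to interpret: a covariate-free
model that predicts the event prevalence $p$ to everyone already scores
$p(1-p)$, so what counts as "good" depends on the outcome frequency. The
index of prediction accuracy removes that dependence by rescaling:

$$\mathrm{IPA} = 1 - \frac{\mathrm{BS}(\text{model})}{\mathrm{BS}(\text{null})},$$

where the null model is the best covariate-free predictor of the setting:
the prevalence (binary), one minus the Kaplan-Meier survival at the
prediction horizon (survival), or the Aalen-Johansen cumulative incidence
of the target cause at the horizon (competing risks). IPA is 100% for a
perfect model, exactly 0 when the model merely matches the null benchmark,
and negative for models whose predictions are worse than ignoring the
covariates — the hallmark of miscalibration. Because the score is computed
at a fixed horizon, IPA is specific to the time frame of the prediction,
which concordance indices for censored data are not.

`ipa_report()` wires these pieces together; the identity
`ipa = 1 - model_brier / null_brier` holds exactly in the returned record,
and the null-fixed-point property (a model predicting the null risks scores
IPA 0 to machine precision) is enforced by the test suite in all three
settings.

## Estimation under right censoring

At horizon $t$ the outcome status $Y_i(t) = \mathbf 1\{T_i \le t,
\text{cause} = k\}$ is unknown for subjects censored before $t$. The Brier
score is therefore estimated by inverse probability of censoring weighting
(IPCW): with $\hat G$ the reverse Kaplan-Meier estimate of the censoring
survival function,

* subjects observed to fail (from *any* cause) by $t$ get weight
  $1/\hat G(T_i-)$,
* subjects still event-free at $t$ get weight $1/\hat G(t)$,
* subjects censored at or before $t$ get weight 0.

Three conventions deserve mention, since the estimator is only defined once
they are fixed:

* **Ties.** At tied times, events are ordered before censorings.
  Consequently the at-risk set of the censoring estimator at $t$ excludes
  subjects with an event at $t$. This is the standard convention that keeps
  the weights well defined (an event at an observed censoring time is
  weighted by the censoring survival *just before* that time).
* **Censoring exactly at the horizon.** Such a subject's status at $t$ is
  unknown under the strict-inequality reading $\mathbf 1\{T_i > t\}$, so
  the weight is 0.
* **Marginal censoring model.** $\hat G$ is estimated unconditionally. If
  censoring depends strongly on covariates the weights are misspecified;
  covariate-dependent censoring models are out of scope.

A horizon at which $\hat G$ has no mass left — or beyond the largest
observed time — is not identifiable; `brier_ipcw()` refuses it with an
error, and `ipa_curve()` drops such horizons with a warning instead of
failing the whole sweep. On uncensored data every weight is 1 and
`brier_ipcw()` reduces *exactly* to the binary Brier score of the event
indicators; the suite asserts bitwise equality on hundreds of random
samples.

The estimators themselves (`kaplan_meier()`, `reverse_kaplan_meier()`,
`aalen_johansen()`) are computed from a shared risk table of the sample's
counting processes, which buys an exact conservation law: at every time,
the cause-specific cumulative incidences and the all-cause survival sum to
one to within 10^-12. All three return a `step_function`, a
right-continuous piecewise-constant curve with left-limit evaluation
(needed for $\hat G(T_i-)$); evaluation beyond the last jump returns the
last value, with horizon validity enforced by the metrics, not the curves.
Agreement with `survival::survfit` (including the multi-state estimator)
is verified in the tests, which keeps the hand-rolled counting-process code
honest without making an external package part of the measure.

## Risk models

The fitters exist to produce horizon-specific risks for validation, not to
replace a modelling package:

* `fit_logistic()` wraps `stats::glm`; fits flagged by the separation
  heuristic (fitted probabilities pinned at 0/1, or slope magnitudes above
  15 on the linear scale) raise an error instead of returning an unstable
  model.
* `fit_cox()` wraps `survival::coxph` with **Breslow tie handling** and the
  Breslow baseline hazard (`basehaz(centered = FALSE)`), so the baseline
  increments at a covariate-free fit are exactly the Nelson-Aalen
  increments $d_j/n_j$.
* `fit_cause_specific()` fits one Cox model per cause, treating
  other-cause events as censored; specifications may differ per cause.

Absolute risk of cause $k$ by $t$ given covariates $x$ combines the
cause-specific hazards (Benichou-Gail):

$$\hat F_k(t \mid x) = \sum_{u_j \le t} \hat S(u_j- \mid x)\,
  e^{x'\beta_k}\, d\hat\Lambda_{0k}(u_j),$$

where $\hat S(\cdot \mid x)$ is the **discrete product-limit** over the
all-cause hazard increments,
$\prod_{u_l < u_j} \bigl(1 - \sum_k e^{x'\beta_k} d\hat\Lambda_{0k}(u_l)\bigr)$.
The product-limit form (rather than $\exp(-\Lambda)$) is a deliberate
design choice, applied to the single-cause Cox model as well: it makes the
covariate-free fit reproduce the Aalen-Johansen estimator (and $1 -$
Kaplan-Meier for one cause) *exactly*, a testable anchor that the
exponential form misses by a first-order tie-dependent amount. Per-subject
hazard increments are clipped below 1 so the product stays non-negative
for extreme linear predictors, and returned risks are clipped to $[0,1]$;
they are non-decreasing in $t$ by construction.

Continuous predictors can carry declarative unit transforms
(`log2` for effects per doubling, `scale = 5` for effects per 5 units) so
reported odds/hazard ratios match clinical reporting conventions;
categorical predictors carry an explicit reference level.

## Variable importance: drop-one IPA gain

`drop_one_ipa()` refits the model on the learning data with one variable
removed — **refit**, not coefficient-zeroed, because the question is what
the remaining variables achieve on their own — and reports
`ipa_gain = IPA(full) - IPA(reduced)` on the validation data. Categorical
variables are dropped as whole blocks (all indicator columns together), one
table row per declared variable, in declaration order. In the
competing-risks setting variables are dropped from the target-cause model
only. Every row is scored against the *same* null Brier score as the full
model (asserted bitwise in the code), so gains are comparable; a reduced
fit that fails is flagged in its row rather than silently omitted.

Two readings of "null model" are both defensible: re-estimated on the
validation sample (the default here), or an intercept-only model carried
over from the learning sample. `null_source = "learning"` selects the
second. The choice matters little when the two samples come from one
population split at random, but the option keeps both interpretations
available; under `"learning"`, a single-predictor model's gain equals the
full-model IPA exactly, since its reduced model *is* the transported null.

## The simulation experiment

`run_fig2()` studies how IPA reacts to discrimination and miscalibration
with uncensored binary data: a single predictor $X \sim N(0,1)$, outcomes
from a logistic model whose log odds ratio $b$ sweeps a grid in $[-1, 1]$.
For each grid point and repetition, three learning sets of $n = 1000$ are
generated with marginal prevalences 40%, 25% and 10%, and a model fitted
on each is evaluated — IPA against the validation prevalence null, and
AUC — on an independent validation set of $n = 200$ with prevalence 40%.
The defaults (21 grid points, 50 repetitions) are the experiment's stated
conditions, not tuning knobs. The model trained at 40% prevalence is
calibrated for the validation population; the 25% and 10% models are
increasingly miscalibrated while having *identical* discrimination. The
experiment shows IPA separating the two properties: at $b = 0$ the
calibrated model's IPA falls to about 0 (useless), the miscalibrated
models' IPA is clearly negative (harmful), while AUC sits at 0.5 for all
three — blind to the difference.

The intercept that achieves a target marginal prevalence solves
$E[\operatorname{expit}(a + bX)] = p$ by adaptive quadrature plus root
bracketing (`solve_intercept()`, achieved prevalence within $10^{-6}$).
Seeding uses one master seed from which a Lehmer-style hash spawns an
independent substream per (grid point, repetition, arm), all below
$2^{31}$; runs are bit-reproducible, and a degenerate single-class
validation draw is redrawn from a bumped stream with a logged message.
Each repetition draws a fresh validation set rather than reusing one fixed
set, so the Monte-Carlo error of the reported means is honest.

`simulate_survival()` generates the censored fixture data: exponential
cause-specific event times with proportional-hazards covariate effects,
independent exponential censoring, status by the minimum. The defaults —
two causes at baseline rates 0.15 and 0.05 per time unit (a dominant
progression-type cause and a rarer competing death), effects 0.7/0.5 on a
standard-normal and a Bernoulli(0.4) covariate for cause 1, an age-like
effect 0.3 for cause 2, censoring rate 0.10 — sketch an active-surveillance
cohort with roughly 20–30% censoring over the follow-up window. This
emulates the *structure* of such studies (mixed covariates, right
censoring, two competing causes), not any particular dataset: constant
hazards, exactly proportional effects and covariate-independent censoring
are idealisations, so passing tests demonstrate correctness of the
estimators under the model, not robustness to real-data violations such as
time-varying effects or informative censoring.

## Numerical choices

* Logistic/Cox convergence: the underlying fitters' criteria with the
  iteration cap raised to 100; undefined (aliased) Cox coefficients are an
  error.
* `solve_intercept()`: quadrature relative tolerance $10^{-12}$, root
  tolerance $10^{-10}$ on $[-40, 40]$.
* Calibration curves use equal-frequency bins (deciles by default; the
  binning is configurable since no canonical rule exists). When the model
  emits few distinct values — a constant model, or risks equal to outcomes
  — quantile breaks collapse, and binning falls back to grouping by exact
  predicted value.
* Exact identities (null fixed point, conservation, IPCW-equals-binary,
  the Aalen-Johansen anchor) are tested at $10^{-10}$–$10^{-14}$;
  Monte-Carlo checks use 3 standard errors at their stated sample sizes.
* IPA is carried in percent in human-readable output and as full-precision
  fractions in machine-readable output; tables round to 2 decimals.

Test and experiment problem sizes are chosen to make sampling error small
relative to the assertion bands while keeping the default suite quick:
parameter-recovery fits use $n = 10^4$–$10^6$, closed-form estimator
comparisons $n = 5000$, the simulation experiment its full stated scale
(21 × 50 × 3 model fits).

## Limitations

IPA is an average-performance measure: it can miss improvements confined
to a small subgroup, it depends on the marginal outcome frequency (so
values are not comparable across populations), and it does not weigh the
costs and benefits of the clinical decision — no decision-curve or
cost-weighted variant is provided. Confidence intervals for the estimators
and for IPA itself, Fine-Gray subdistribution regression (external
subdistribution-model predictions can still be *scored* through the risk
interface), time-dependent AUC, left truncation and interval censoring are
out of scope.
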