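---
title: "Screening risk factors of elevated childhood blood lead with the group Lasso"
author: "bllasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening risk factors of elevated childhood blood lead with the group Lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bllasso)
```

## The scientific setting

Children living near informal electronic-waste (e-waste) recycling sites are
chronically exposed to lead. Surveillance studies in such settings collect,
per child, a blood lead level (BLL, µg/dL), anthropometrics, and a few dozen
coded questionnaire items on behavior, diet, and the household environment.
Two analytic questions recur:

1. **Description** — do BLLs differ between the exposed and a reference
   area, overall and within sexes, and which characteristics differ between
   children with elevated (BLL ≥ 10 µg/dL, the public-health action
   threshold) and non-elevated BLLs?
2. **Risk-factor screening** — which questionnaire items discriminate the
   elevated from the non-elevated children, when each multi-category item
   should be kept or discarded *as a whole*?

`bllasso` implements both, plus the resampling machinery used to judge
whether a screened factor is robust, and a seeded synthetic-data generator
so the full pipeline is testable without access to any original survey.

## The model

Write $Y_i \in \{0,1\}$ for the elevated-BLL indicator and
$x_i = (x_{i1}, \dots, x_{iG})$ for the covariates, where covariate $g$
contributes a block of $df_g$ dummy columns (a $k$-category item yields
$k-1$ indicators against its first, reference, category; a continuous
covariate is a singleton block). The conditional probability is logistic,

$$
\log \frac{P(Y_i = 1 \mid x_i)}{1 - P(Y_i = 1 \mid x_i)}
  = \beta_0 + \sum_{g=1}^{G} x_{ig}^\top \beta_g ,
$$

and the estimator minimizes the per-observation penalized negative
log-likelihood

$$
Q_\lambda(\beta_0, \beta) \;=\;
  \frac{1}{n} \sum_{i=1}^n \Big[ \log\big(1 + e^{\eta_i}\big) - y_i \eta_i \Big]
  \;+\; \lambda \sum_{g=1}^G \sqrt{df_g}\, \lVert \beta_g \rVert_2 .
$$

The group penalty zeroes whole blocks, so a questionnaire item is selected
or dropped jointly across its dummies. The $\sqrt{df_g}$ rescaling is the
standard degrees-of-freedom correction so that blocks of different size
compete on even terms. The intercept is never penalized. With all blocks of
size one the estimator reduces to the classical Lasso; no separate code
path exists for that case.

The $1/n$ loss scaling matters for interpretation: it makes $\lambda$ and
the cross-validated deviance per-observation quantities. The intercept-only
deviance at an event rate of 30% is
$-2(0.3\log 0.3 + 0.7\log 0.7) = 1.2217$, which is the yardstick against
which a tuned deviance just below 1.2 should be read.

## The solver

`fit_grplasso()` uses block-wise **group descent**. Before fitting, every
block is centered and orthonormalized ($Z_g^\top Z_g / n = I$;
`standardize_groups()`), and the affine per-block transform is stored so
coefficients map back to the original covariate scale exactly. The
logistic curvature is globally bounded by $1/4$, so at the current iterate
the loss restricted to block $g$ is majorized by a separable quadratic and
the block minimizer is the closed-form group soft-threshold

$$
\beta_g \leftarrow \Big(1 - \tfrac{4\lambda\sqrt{df_g}}{\lVert z_g\rVert}\Big)_+ z_g,
\qquad z_g = \beta_g + \tfrac{4}{n} Z_g^\top (y - p).
$$

Each block step is a majorize–minimize step, so the objective is
non-increasing at every sweep — the property the test suite asserts
iteration by iteration. A full-IRLS reweighting per block step was
considered and rejected as the default: with orthonormalized blocks the
IRLS subproblem loses its closed form, and the fixed-curvature step is the
variant that carries the descent guarantee. The price is a conservative
step length; the solver compensates in three monotonicity-preserving ways:
active-set cycling (full sweeps establish the active set, cheap sweeps
over active blocks do the bulk of the descent); exploiting that a
standardized $k$-dummy block takes only $k+1$ distinct row patterns, which
reduces its gradient to per-category residual totals; and an
accept-if-better extrapolation — after each sweep a geometric line search
along the sweep direction (the linear predictor is affine in the
coefficients, so each trial costs one objective evaluation) is accepted
only when it strictly lowers the objective, which shortcuts the slow
linear convergence of fixed-curvature majorization.

In multi-$\lambda$ (path) solves only, the path is truncated — the current
solution carried forward — once the training fit is near-saturated (over
90% of the null deviance explained; with $p$ of the order of $n$ that is
noise interpolation far beyond any cross-validation minimum) or at the
first $\lambda$ that exhausts its iteration budget, which with warm starts
marks the onset of (quasi-)separated coefficient drift. Single-$\lambda$
fits never truncate. The guard matters for the resampling machinery:
bootstrap resamples hold ~37% duplicated records and routinely become
separable deep in the path, where refining fits that no selection
criterion can choose would dominate the compute budget.

Numerical choices: convergence is declared when the largest coefficient
change in a sweep falls below `tol = 1e-6`, with `max_iter = 1000` sweeps
per $\lambda$ (non-convergence returns the fit with `converged = FALSE`
and a warning — typical only for (quasi-)separated data at vanishing
$\lambda$). Probabilities are maintained as $w = e^\eta$ with $\eta$
clamped at $\pm 500$; the all-null solution at $\lambda_{\max}$ is made
exact by a $10^{-10}$ relative dead-band in the threshold. Solutions are
certified post hoc by `kkt_check()`: active blocks must have gradient norm
equal to $\lambda\sqrt{df_g}$, inactive blocks at most that.

`grplasso_path()` solves a log-spaced grid of 100 values from
$\lambda_{\max}$ (the smallest all-null penalty,
$\max_g \lVert Z_g^\top(y-\bar y)\rVert / (n\sqrt{df_g})$) down to
$10^{-3}\lambda_{\max}$, warm-starting each fit.

## Tuning and validation

`cv_grplasso()` performs 10-fold cross-validation of the per-observation
binomial deviance. Folds are stratified on the outcome — with ~72 design
columns on a few hundred records, unstratified folds too easily lose a
class. Within each training split the orthonormalization is **recomputed**,
so no information leaks from held-out records through the standardization.
The operating $\lambda$ is the strict minimizer of the mean deviance, with
exact ties broken toward the larger (sparser) value; no one-standard-error
rule is applied. Note that the strict CV minimum is a mildly liberal
selector: under pure noise it keeps at most one active group in only about
three quarters of replicates (measured by simulation in the test suite),
not always.

`bootstrap_stability()` and `permutation_stability()` repeat the *entire*
tuned pipeline — re-encode, re-standardize, re-tune, re-fit — on resampled
data and report per-group selection frequencies. Bootstrap replicates draw
$N \in \{150, 200, 250\}$ records with replacement; permutation replicates
draw a stratified subsample whose elevated proportion matches the source
exactly and then shuffle the outcome labels within it, so class counts are
fixed and any selection is spurious. The permutation scheme was chosen to
satisfy both readings of "fixing the proportion during resampling":
the subsample is proportion-preserving *and* the labels are permuted.
Replicate seeds derive from the master seed by a counter; replicates whose
outcome collapses to a single class are redrawn and counted. Dummy columns
for categories absent from a small resample are dropped for that replicate
(the group shrinks accordingly) rather than aborting on a rank-deficient
block.

## The synthetic survey generator

`generate_survey()` emulates the structure the analysis assumes, not any
child's real data:

* **Cohort**: `n_children` (default 823) split between an exposed and a
  reference area (default 60.3% exposed); age from a truncated normal
  (mean 4.62 y, sd 1.13 y, range 1.5–10.9 y); anthropometrics linear in
  age with realistic residual spread.
* **Questionnaire**: the default codebook holds 31 covariates — 4
  continuous anthropometrics and 27 categorical items — expanding to 72
  dummy columns. Category probabilities default to plausible frequency
  profiles; only e-waste proximity is area-dependent (40% yes in the
  exposed area, 5% in the reference area).
* **Blood lead margins**: per area, BLL is log-normal with the medians and
  IQRs conventionally reported for such settings (defaults: exposed median
  7.06, IQR 4.71; reference 5.89, IQR 3.54 µg/dL). `lognormal_params()`
  recovers $(\mu, \sigma)$ from a median–IQR pair by a root find with the
  IQR reproduced to $10^{-8}$.
* **Outcome mechanism**: elevated status is drawn *first* from the
  logistic mechanism (default true effects: girl $\ln 0.51$, e-waste
  proximity $\ln 2.28$; all other groups 0), then BLL is drawn from the
  log-normal truncated to the matching side of 10 µg/dL. When the
  intercept is left unspecified it is calibrated per area so the
  cohort-average elevated probability equals the log-normal tail above the
  threshold; the truncated halves then reassemble the exact log-normal, so
  continuous margins and odds-ratio structure hold *simultaneously*.
* **Missingness** is missing-completely-at-random with per-field rates —
  no mechanism beyond that is modeled.

What the generator deliberately does **not** emulate: household or sibling
clustering, item-level response correlation, measurement error in the
assay, informative missingness, or real questionnaire wording. Passing
tests on these synthetic cohorts therefore demonstrates that the machinery
is correct and calibrated, not that any particular real-world association
holds.

### A note on attainable power

At the default effect sizes (odds ratios 0.51 and 2.28) and the
questionnaire-analysis size of 334 children with a ~24% event rate, even
the oracle unpenalized logistic fit yields Wald $|z|$ statistics of only
about 2.5 (sex) and 3.3 (e-waste proximity). Joint selection of both
groups by the CV-tuned group Lasso occurs in roughly two thirds of
replicates — an information-theoretic ceiling of the design, not a solver
deficiency: published survey data of this kind evidently carried a
stronger realized signal than these marginal odds ratios imply. The
bootstrap ranking property (the two true groups have the top-2 selection
frequencies) is robust at these sizes; a near-universal joint-selection
rate is not.

## Problem sizes used by the automated checks

The test suite and the acceptance script regenerate everything they
measure: solver oracles on ~20 random instances with $n \le 100$,
$p \le 13$; calibration checks at $n = 10^5$ (margins) and $n = 10^4$
(mechanism recovery); tuned-selector replication with 100 cohorts of
$n = 334$; stability with $B = 100$ replicates at $N = 250$ (bootstrap)
and $N = 200$ (permutation). These sizes mirror the surveillance setting
the package targets while keeping a full run on a single CPU within
minutes.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_children = 823, seed = 1)
survey <- generate_survey(cfg)
describe_survey(survey)

enc <- encode_survey(survey[survey$area == "exposed", ])
cv <- cv_grplasso(enc, seed = 1)
cv
coef(cv$selected_fit)[coef(cv$selected_fit) != 0]

boot <- bootstrap_stability(survey[survey$area == "exposed", ],
                            N = 250, B = 100, seed = 1)
boot
```

## Limitations

* Complete-case analysis only; no imputation is offered because none is
  assumed by the methodology being implemented.
* Ordinal items are dummy-coded like nominal ones (no score coding), and
  no interactions, splines, elastic-net or overlapping-group variants are
  provided.
* The unpenalized reference fit refuses separated designs rather than
  regularizing them; that is deliberate — the penalized fit is the answer
  in that regime.
* Percentages are computed over non-missing denominators, matching how
  published survey tables reconcile; strata with empty denominators report
  an undefined percentage rather than an error.
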