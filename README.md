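# bllasso

Group-Lasso screening of risk factors for elevated childhood blood lead
levels (BLLs), with the descriptive epidemiology and resampling validation
that surround it in population surveillance studies near e-waste recycling
sites.

## Who this is for

Epidemiologists and biostatisticians analyzing child-level surveys in which
a biomarker (BLL, µg/dL) is paired with a few dozen coded questionnaire
items (behavior, diet, household environment) and the question is which
items discriminate children with **elevated** BLL (≥ 10 µg/dL, the
public-health action threshold) from the rest — keeping or discarding each
multi-category item *as a whole*, not dummy by dummy.

## The model

With $Y_i \in \{0,1\}$ the elevated indicator and covariate $g$ expanding
to a block $x_{ig}$ of $df_g$ dummy columns (reference category omitted),
the estimator is the group-Lasso penalized logistic regression

$$\hat\beta = \arg\min_{\beta_0,\beta}\; \frac{1}{n}\sum_{i=1}^n
\left[\log(1+e^{\eta_i}) - y_i\eta_i\right]
+ \lambda \sum_{g=1}^{G}\sqrt{df_g}\,\lVert\beta_g\rVert_2,
\qquad \eta_i = \beta_0 + \textstyle\sum_g x_{ig}^\top\beta_g,$$

optimized by group descent over orthonormalized blocks (closed-form group
soft-threshold under a 1/4 curvature majorization; monotone descent with a
KKT certificate at the solution). The penalty level $\lambda$ is tuned by
10-fold cross-validated per-observation binomial deviance; selection
robustness is assessed by selection frequencies over 100 bootstrap
resamples and checked against permutation nulls at several sample sizes.
A seeded synthetic survey generator reproduces the relevant data structure
(two areas with log-normal BLL margins, 31 covariate groups expanding to
72 dummies, a logistic outcome mechanism) so everything is testable
without access to any original survey.

## Worked example

```r
library(bllasso)

cfg    <- sim_config(n_children = 823, seed = 1)   # synthetic cohort
survey <- generate_survey(cfg)
describe_survey(survey)
```

```
BLL by area, µg/dL:
       area   n median  iqr
1   exposed 499   7.28 4.19
2 reference 324   5.78 3.65

Elevated BLL by area:
    stratum n_elevated n_total percent
1   exposed        109     499   21.84
2 reference         37     324   11.42

Area t-test on log(BLL): p = 2.07e-08; ANCOVA-adjusted: p = 1.22e-08
```

The exposed-area children carry a markedly higher lead burden (median 7.28
vs 5.78 µg/dL; 21.8% vs 11.4% elevated), and the area contrast survives
adjustment for age, height and weight.

```r
enc <- encode_survey(survey[survey$area == "exposed", ])
cv  <- cv_grplasso(enc, seed = 1)
cv
```

```
10-fold CV over 100 lambdas
  selected lambda = 0.02537, mean deviance = 1.004 (SE 0.00998)
  active groups at selection: sex, ewaste_proximity, calcium_supplement,
                              toy_mouthing, floor_dust
```

```r
cc <- coef(cv$selected_fit)
round(cc[cc != 0], 4)
```

```
         (Intercept)             sex.girl ewaste_proximity.yes  ...
             -1.3621              -0.3797               0.6625  ...
```

The two covariates the generator actually wired into the outcome — sex
(girls protected, coefficient −0.38, OR ≈ 0.68 after shrinkage) and
e-waste proximity (coefficient 0.66, OR ≈ 1.94) — carry the largest
penalized coefficients; the remaining selected groups are small-coefficient
CV-minimum extras, which is exactly what the stability analysis is for:

```r
boot <- bootstrap_stability(survey[survey$area == "exposed", ],
                            N = 250, B = 100, seed = 1)
```

ranks groups by how often the full tuned pipeline re-selects them across
bootstrap resamples, and `permutation_stability()` verifies that nothing
is selected systematically once the outcome labels are shuffled.

A thin command-line wrapper with subcommands `simulate`, `describe`,
`fit`, `cv`, `stability`, `run` is installed under `exec/bllasso`.

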