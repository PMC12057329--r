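---
title: "Personalized advantage indices for guided self-help: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized advantage indices for guided self-help: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paimatch)
```

## The problem

Low-intensity guided self-help (GSH) comes in more than one flavour — here,
a cognitive analytic variant (CAT-GSH) and the standard cognitive
behavioural variant (CBT-GSH) for anxiety. Patients differ in which variant
they would respond to best, and in a preference trial they largely choose
their own arm. The personalized advantage index (PAI) asks the data which
arm each patient *should* have received: fit a separate outcome model per
arm, predict every patient's post-treatment GAD-7 score under both arms,
and take the difference

$$\mathrm{PAI}_i = \hat y_i^{\mathrm{CBT}} - \hat y_i^{\mathrm{CAT}},$$

so a positive value means the model expects a lower (better) anxiety score
under CAT-GSH. Patients whose received arm matches the indicated arm form
the "optimal" group; comparing their endpoints with the "non-optimal" group
estimates what treatment matching would have bought.

`paimatch` implements that full pipeline — per-arm preprocessing, two
variable-selection methods, leave-one-out cross-validated (LOOCV) linear
models, counterfactual scoring, PAI classification, and the endpoint
statistics — together with a synthetic preference-trial generator whose
true individual treatment effects are known, so every stage can be
validated against ground truth.

## The synthetic trial generator

Real trial data of this kind are not public, so the generator emulates the
published sample structure: two arms with a strong preference skew
(default P(CAT) = 154/209), about 6% randomized allocation, and sixteen
baseline covariates whose marginals follow the published baseline table
(75.6% female, 12.9% unemployed, IMD decile 4.14 ± 2.77, baseline GAD-7
13.62 ± 4.81, PHQ-9 13.65 ± 5.59, WSAS 18.69 ± 8.57, BAI 25.50 ± 9.82,
and so on; the previous-CBT rate, never published, is set to a plausible
30%). The post-treatment outcome is linear on the encoded covariates:

$$y^{post}_i = \beta_0(\text{arm}_i) + \sum_j \beta^{prog}_j x_{ij}
  + \mathbf{1}[\text{arm}_i = \text{CAT}] \sum_j \beta^{presc}_j x_{ij}
  + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with covariates on their analysis encoding (z-scores for continuous,
±0.5 for binary), so coefficients read as GAD-7 points per SD or per
contrast. Prognostic coefficients move the outcome in both arms;
prescriptive ones only in CAT, and they alone drive the true advantage

$$\mathrm{PAI}^{true}_i = \beta_0(\text{CBT}) - \beta_0(\text{CAT})
  - \sum_j \beta^{presc}_j x_{ij},$$

which `oracle_true_pai()` returns exactly. Design choices worth knowing:

* **Bounded integer scales.** Questionnaire scores are Gaussian draws
  rounded and clipped to their ranges (GAD-7 0–21, PHQ-9 0–27, WSAS 0–40,
  BAI 0–63). Clipping is the simplest defensible boundary policy; it
  slightly compresses effects near the scale ends, which is why oracle
  correlations are checked "up to clipping".
* **Follow-up scores** are an autoregressive blend,
  `carry * post + (1 - carry) * baseline + noise` with `carry = 0.8` by
  default: no published follow-up model exists, and an AR blend produces
  realistic three-point trajectories for the mixed ANOVA stage.
* **Missingness** is MCAR at a configurable cell rate, or MAR with
  missingness probability logistic in the standardized baseline GAD-7
  (severity-dependent nonresponse), which is what the imputer has to cope
  with in practice.
* **Sessions** come from a dropout/engager mixture so that the ≥2-session
  treatment-episode filter has something to do; the published filter
  excluded 62 of 271, i.e. a 23% sub-episode rate.
* **Defaults are study conditions, not dials**: `noise_sd = 4` GAD-7 points
  matches the published LOOCV RMSE range (4.0–4.5); `preset_null()` sets
  all prescriptive effects to zero; `preset_strong()` uses two prescriptive
  coefficients (2.5 for unemployment, 2.0 per PHQ-9 SD), a regime where
  matching genuinely matters.

What the generator does **not** emulate: session-by-session trajectories,
therapist effects, informative dropout beyond the session count, covariate
correlation structure (covariates are drawn independently), or selection
effects of preference on outcome. Passing tests therefore show the
pipeline recovers known structure of this generative family; they cannot
show the real trial's effects are true.

## Preprocessing

Each arm is processed separately throughout — imputation forests and
encoding moments never see the other arm, mirroring the per-arm modelling.

* **Episode filter**: keep patients with ≥ 2 attended sessions.
* **Missingness screen**: drop predictors whose missing fraction is
  strictly above 0.5 (the published analysis dropped marital status at 86%
  missing; no threshold was stated, so we use a conservative half, with
  the boundary kept — a predictor at exactly the threshold survives).
* **Imputation** is missForest-style chained random-forest imputation:
  mean/mode initialization, then iterative per-variable forests refreshing
  the missing cells in order of increasing missingness, stopping when the
  change criterion (sum of squared differences for continuous,
  disagreement count for categorical) first rises, capped at 10 sweeps.
  Deterministic given a seed; observed cells are never altered.
* **Encoding**: continuous predictors are z-scored on the arm's own
  analysis sample; binaries are coded −0.5/+0.5 with the +0.5 level fixed
  alphabetically and recorded, so sign conventions are reproducible;
  multi-level categoricals collapse to documented binaries; zero-variance
  predictors are dropped with a warning. Baseline GAD-7 is encoded but held
  out of the candidate set: it enters every outcome model by forced entry,
  controlling for initial severity. The allocation route joins the
  candidates as a derived preference flag. The encoding metadata travels
  with fitted models so cross-arm patients are scored on the scale the
  model was trained on.

## Variable selection

Two deliberately different methods screen the candidates per arm:

* **Boruta** (shadow-feature random forest, implemented in-package over
  `ranger` permutation importance): each iteration augments the candidates
  with row-permuted shadow copies, fits a forest, and scores a "hit" for
  every candidate whose importance exceeds the best shadow's. A two-sided
  binomial test at α = 0.01 (Bonferroni-adjusted across candidates)
  confirms or rejects; rejected candidates leave the forest, confirmed
  ones stay in (removing them would let chance correlations of the
  remaining noise masquerade as signal). Defaults: 500 trees, up to 100
  iterations. Undecided candidates end tentative and are *included*
  downstream — tentative means "ranked above at least one shadow", and
  the downstream LOOCV comparison arbitrates. A reduced two-shadow variant
  is available behind a flag for comparison with the loop described
  loosely in some write-ups.
* **Elastic net** (`glmnet`, mixing parameter 0.5, 10-fold CV): selected
  set = nonzero coefficients at the one-SE lambda. The one-SE rule favours
  sparsity, which is the point of penalized screening here.

Both are deterministic given a seed and invariant to candidate column
order (candidates are processed in fixed name order internally).

A behaviour worth stating plainly, measured in the acceptance suite: on
pure-noise data (n = 200, 10 candidates), the shadow-feature method
confirms on average about one candidate per run — features whose chance
in-sample correlation (|r| ≈ 0.15) makes them genuinely informative
in-sample. This is a property of all-relevant selection at this sample
size, not of the implementation (an independent reimplementation using
scaled z-score importances measures the same level). It is one reason the
pipeline runs a second, penalized selection method and compares the two
by held-out error, and it echoes the known overfitting concern for
forest-based selection with few candidates.

## Outcome models and method choice

For each arm and each selected set, an ordinary least squares model
(selected predictors + forced baseline GAD-7 + intercept) is evaluated by
leave-one-out cross-validation, computed exactly via the linear-smoother
identity $\hat y_{(-i)} = y_i - e_i/(1 - h_{ii})$ (verified in tests
against literal refitting). Reported metrics: RMSE, MAE, Pearson r
between held-out predictions and observations, and two R² variants — the
variance-explained form 1 − SSE/SST on held-out predictions (the default,
which can be negative) and squared Pearson r. Both are reported because
published metric pairs of this kind (e.g. R² = .33 alongside r = .64) are
inconsistent with R² = r², so the variance-explained reading is taken as
primary and the other shown alongside.

The preferred method per arm follows "lowest error and highest
correlation": a method dominating on (RMSE, MAE, r) wins; an exact tie on
all metrics — which happens when both methods select identical variables —
defers to the other arm's winner, so both arms end on the same method
(congruence); a genuine metric conflict is resolved by RMSE, error being
listed first in the rule. The final per-arm model is the post-selection
OLS refit on the arm's full analysis sample, with no shrinkage: the
penalty was a screening device, not the estimator.

## PAI, groups, subgroup

Both counterfactual predictions come, by default, from the final full-arm
models, applied to the full sample through each model's own encoding
snapshot; predictions are not clipped to the scale. `pai = yhat_cbt -
yhat_cat`; positive indicates CAT, negative CBT, exactly zero indicates
no treatment (excluded from both groups — a measure-zero event under
continuous predictors, so no arbitrary tie rule is imposed). A
DeRubeis-style variant (`loocv_own_arm = TRUE`) replaces each patient's
own-arm prediction with their held-out LOOCV prediction. The default
follows the published analysis; the variant matters for validation,
because in-sample own-arm predictions correlate with the observed outcome
through fitting optimism, which enriches the "optimal" group with
good outcomes. In null simulations (no prescriptive effects, 20 seeds)
the default variant rejects at nominal α = .05 in 3/20 runs, the held-out
variant in 2/20; the acceptance suite therefore validates the matching
machinery under the held-out variant, and users comparing optimal against
non-optimal groups on real data should be aware of the optimism in the
default.

The large-benefit subgroup takes |PAI| as its basis: threshold =
mean(|PAI|) + 1·SD(|PAI|), membership |PAI| ≥ threshold. Using the
absolute value lets both CAT-indicated and CBT-indicated patients qualify,
which matches how both arms appear in the published subgroup; for
non-members, no optimal treatment is considered indicated. If the basis
has zero variance the threshold collapses to the common value and all
patients qualify (logged).

## Endpoint statistics

* **RCSI** (reliable and clinically significant improvement): change from
  baseline ≥ 4 GAD-7 points AND end score strictly below the clinical
  cut-off of 8.
* **2×2 chi-square**: uncorrected Pearson statistic, df = 1 — the
  published tables reconstruct to the uncorrected statistic, so no Yates
  correction is applied. A property test checks the algebraic shortcut
  $n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ on random tables.
* **Odds ratio**: non-optimal odds over optimal odds (values < 1 mean the
  non-optimal group fared worse, reproducing the published orientation).
  Zero cells error by default; the Haldane–Anscombe +0.5 policy is opt-in
  and used inside the pipeline so small subgroups still report.
* **Pooled two-sample t from summaries** reconstructs baseline-table
  comparisons from printed means/SDs/sizes; df = n₁ + n₂ − 2.
* **Counts from percentages** round half-up, the convention that
  reproduces published counts from published percentages.
* **Mixed ANOVA**: classical split-plot decomposition for 2 groups × k
  times on complete cases (incomplete subjects excluded listwise, logged).
  The between stratum is a one-way ANOVA on subject means. The within
  stratum uses the weighted-means decomposition, which keeps the total SS
  exactly additive for unbalanced groups and coincides with the usual
  Type III table under balance. Sphericity diagnostics operate on the
  pooled within-group covariance of orthonormalized contrast scores:
  Mauchly's W with the standard Box chi-square approximation, and
  Greenhouse–Geisser ε = (tr C)²/((k−1) tr C²), clamped to
  [1/(k−1), 1]; within-effect dfs and p-values are GG-corrected, and
  partial η² = SS_effect/(SS_effect + SS_error) per stratum. With k = 2
  there is a single contrast and ε ≡ 1. Tests check the SS against a
  first-principles oracle at 1e-10, Mauchly/ε/F against `car`, and the
  Mauchly rejection rate against its nominal α under a spherical
  generator.

## Numerical and degenerate-input policy

Singular design matrices raise errors naming the problem (including the
per-fold leverage check h ≈ 1 in LOOCV); constant outcomes raise a
degenerate-outcome error in selection and an undefined-correlation error
in metrics; zero marginals make the chi-square error rather than return
0/0; entirely-missing variables are unimputable and say so. Derived child
seeds keep every random stream (arm assignment, covariates, noise,
missingness, per-iteration forests, CV folds) independent yet fully
reproducible from one user-facing seed.

## Problem sizes used in validation

The test suite exercises: LOOCV vs brute force on 20 random instances
(n ≤ 60); ANOVA oracle equivalence on 8 random small designs plus a
500-replicate Mauchly calibration at n = 50, k = 3; 1,000 random tables
for the chi-square shortcut; 20 seeded Boruta runs (n = 200, p = 10) for
the true-feature property and 50 for the null; 20 elastic-net replicates
at n = 300; PAI parameter recovery on 20 trials of 4,000 patients
(balanced arms, noise SD 3, prescriptive effects ≥ 2 points), where the
estimated PAI correlates with the oracle at ≥ 0.7 and agrees in sign for
≥ 80% of patients with |oracle| ≥ 1; and 40 end-to-end pipeline runs at
the published sample size of 209.

## Known limitations

* The per-arm CBT-sized samples (~55) make the CBT model noisy, exactly as
  the published analysis warns; the pipeline reports but cannot repair
  that.
* The generator draws covariates independently; collinearity-driven
  selection pathologies are exercised only through the duplicated-column
  grouping test.
* The ANOVA is the classical split-plot, not a mixed-effects model; no
  multiple imputation of outcomes; propensity-style adjustment for the
  preference skew is out of scope.
* Published headline model metrics and RCSI percentages depend on the
  unreleased trial data; they are validated here only in the
  property-based sense (the printed inferential statistics, by contrast,
  reproduce from printed counts and summaries — see
  `scripts/acceptance.R`).
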