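---
title: "Expert-augmented rule-ensemble models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expert-augmented rule-ensemble models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamlr)
```

## The problem

Machine-learning models for bedside prediction — here, whether a mechanically
ventilated child in an intensive care unit will be successfully extubated —
learn whatever correlations the training data contain, including artifacts of
local practice that do not carry over to other units. A rule-ensemble
("RuleFit") classifier makes those correlations inspectable: gradient-boosted
shallow trees are converted into conjunctive Boolean rules such as
`age <= 10 & respiratory_rate <= 30`, and an L1-penalized logistic regression
selects a sparse linear model over them. Because each selected rule defines a
patient subgroup a clinician can reason about, a panel of experts can audit
the model rule by rule. `eamlr` implements that audit loop and the
re-regularization it drives.

## The model and the expert-augmentation procedure

1. **Rule ensemble.** Boosted trees (leaf-wise, few leaves per tree) are fit
   to the training split. Every root-to-node path — internal nodes included —
   becomes a candidate rule; conditions on the same feature are merged to the
   tightest interval and exact duplicates are removed. The Boolean
   rule-activation matrix feeds an L1-penalized logistic regression
   (unstandardized: rules share the common 0/1 scale, and standardizing would
   silently reweight the penalty by rule support). Rules with exactly-zero
   coefficients are dropped; the intercept is never penalized.

2. **Elicitation.** Each selected rule is rendered as a survey item showing,
   for every variable the rule references, the subgroup's and the full
   training sample's median (minimum, maximum) for numeric variables and the
   mode plus all levels present for categorical ones. Experts answer on a
   five-point Likert scale (1 = much higher chance of success … 5 = much
   lower). Responses are aggregated per rule as the arithmetic mean and the
   sample standard deviation (n − 1 denominator; an n-denominator option
   exists).

3. **Discordance.** Rules are ranked twice by increasing chance of success:
   by training-set empirical risk (the subgroup's success proportion) and by
   the expert mean (descending, since 1 is the most favourable answer). Ties
   receive average (fractional) ranks, which preserves the identity that the
   delta ranks sum exactly to zero. The discordance score is
   `delta_rank / expert_sd`: disagreement counts for more where the panel
   agreed among itself. A unanimous panel would make the ratio infinite, so
   standard deviations are floored at the smallest positive SD observed
   across rules (fallback 0.1 when all are zero), with a warning.

4. **Re-regularization.** The selected rules' coefficients are re-fit on the
   training activation matrix by ridge logistic regression in two variants.
   *Soft:* per-rule penalty factors `|delta_rank/SD|`, normalized to mean 1
   so the shared lambda stays comparable across variants (the convention of
   the penalized-GLM family used for fitting); a factor of zero leaves that
   coefficient unpenalized. Scaling the penalty factor is equivalent to
   dividing the rule's column by the square root of the factor before a
   uniform ridge fit and rescaling the coefficient back. *Hard-k:* the k
   rules with the largest `|delta_rank/SD|` (ties: larger `|delta_rank|`,
   then rule id) are excluded outright and the remainder re-fit under a
   uniform ridge. The default exclusion grid is {1, 3, 5, 7, 10, 11} and is
   fully configurable.

5. **Evaluation.** AUC is the Mann–Whitney probability with ties counted one
   half, so it agrees exactly with brute-force pair counting. Models are
   compared on the internal test and the external test set with a paired
   bootstrap (both models scored on the same resample), percentile 95%
   intervals, 2000 iterations by default. The generalization *change score*
   is external-AUC minus test-AUC; the *difference-in-differences* subtracts
   the baseline model's change score and is the headline quantity: positive
   values mean the expert-augmented model lost less performance externally.

## The synthetic cohort generator

The study data this workflow targets are confidential electronic health
records, so the package ships a parametric emulator used by every test.

* **Structure.** Each intubation contributes a run of 4-hour windows, the
  first ending 12 h after intubation. Numeric features are marginally
  standard normal with AR(1) persistence (default 0.6) across windows;
  categorical features persist between windows with probability 0.8. Every
  feature carries two lagged copies (`_lag1`, `_lag2`; early windows
  backfilled with the earliest value, avoiding a missing-data subsystem) and
  a baseline (`_base`) copy of the window-0 value.
* **Outcome.** Each window's outcome is an independent Bernoulli draw from
  `logistic(intercept + sum of planted-rule effects)`. The real outcome is a
  time-shifted label; the refit mathematics consume only (features, binary
  outcome, cluster id), so the shift is emulated rather than mechanistically
  simulated. An optional within-intubation AR(1) latent term on the logit is
  available for studying cluster dependence; it is off by default.
* **Splits.** The internal cohort splits 80/20 into train/test by intubation
  order index — a stand-in for a date-based split that needs no calendar.
  A separate external cohort (default 250 intubations against 1000 internal)
  uses each planted rule's *external* effect.
* **Planted rules.** The default configuration plants six *stable*
  single-condition rules on common subgroups (~35% support, log-odds effects
  ±1 to ±1.5 carried unchanged into the external cohort) and two *spurious*
  rules on rare subgroups (~8% support, effects −2 and +2 internally, zero
  externally). Spurious effects concentrated in niche subgroups are the
  pattern an artifact rule typically takes — a strong, local, non-portable
  association — and the pattern expert review is meant to catch; a spurious
  effect on a dominant feature would instead smear across most extracted
  rules and could not be removed by excluding a handful of them. The
  intercept is calibrated by root-finding on the realized linear predictor so
  the internal window-level positive rate lands at 0.762.
* **Simulated experts.** An expert's latent score for a rule is the log
  ratio of the subgroup's external-cohort outcome rate to the overall
  external rate (rates floored at 0.5/n to keep the log finite), plus a
  shared panel bias and independent N(0, sd) perception noise (default sd
  0.25), cut at (−0.4, −0.1, 0.1, 0.4) into the five Likert anchors; higher
  latent relative risk maps to a lower Likert value. The default panel has
  25 members — 12 attending physicians, 7 fellows, 4 nurses, 2 respiratory
  therapists — with experience bands (<3, 3–5, 6–10, >10 years) in roughly
  the proportions 24/20/24/32%. Simulated experts therefore "know" the
  external truth up to noise and coarsening: that is precisely the premise
  of the method (expert knowledge generalizes better than local artifacts),
  and the generator makes the premise explicit and controllable.

What the generator does **not** emulate: real physiology or the 98 clinical
variables, correlated features, informative missingness, competing outcomes
(all non-success dispositions are collapsed to 0), record trimming around
death, or experts whose knowledge is biased in structured ways beyond a
shared scalar shift. Passing tests show the machinery is correct and that
the method behaves as intended *when its premise holds*; they cannot show
that real expert panels satisfy the premise.

## Numerical choices

* Tree splits follow the boosting library's `x < t` / `x >= t` routing;
  conditions are recorded with closed-left `<= / >` kinds at the same
  threshold. Histogram-based splitting places thresholds between observed
  values, so the two readings disagree only on exact threshold ties, which
  have probability zero for continuous features. Thresholds are kept at full
  precision internally and rounded for display only.
* One-hot encoded categorical splits are mapped back to level-set membership
  on the original feature (left branch = complement of the level), so
  extracted rules read naturally.
* The L1 and L2 fits use coordinate descent on an unstandardized design with
  a warm lambda path down to the target value and a tight convergence
  threshold (1e-11) for reported coefficients; lambda selection by
  cross-validation uses the solver's default tolerance. Folds are assigned
  at the intubation level (windows of one intubation never straddle folds)
  and the assignment is invariant to row order.
* Under mean-1 normalization a single exploding penalty factor saturates at
  R (the rule count) while the others vanish; the soft variant then
  converges to the model that excludes the discrepant rule only when the
  shared lambda is appreciable. The tests exercise exactly that joint limit.
* Single-column ridge refits (k = R − 1) bypass the coordinate-descent
  solver, which requires two columns, and use BFGS on the identical
  penalized deviance.
* Bootstrap resampling defaults to the intubation (cluster) level because
  windows within an intubation are dependent; window-level resampling is
  available. Single-class resamples are redrawn up to a cap. Percentile
  intervals are used throughout — the simplest defensible choice, and
  configurable in principle to fancier intervals if a need arises.
* Secondary metrics (sensitivity, specificity, balanced accuracy) are
  reported at the threshold maximizing the training-set Youden index.
* Stage seeds derive purely from (global seed, stage name) via a small
  polynomial hash, so every stage is independently reproducible and seeds
  stay below 2^31.

## Design decisions on genuinely open points

* **Rules from all nodes, not only leaves** (`leaves_only` flag): the
  original rule-ensemble formulation takes every node below the root, and
  interior-node rules are exactly the short, auditable subgroups experts can
  assess.
* **No linear terms in the selection design**: the selection stage operates
  on the Boolean rule matrix alone, keeping every model term an auditable
  subgroup.
* **Ridge refits are logistic-linked.** The outcome is binary and evaluated
  by AUC; an identity-link refit of a binary outcome would leave the
  probability scale. (The single-column special case shares the same
  logistic objective.)
* **Ridge lambda is re-tuned by cross-validation per variant** rather than
  inherited from the selection stage; the two penalties are not on a common
  scale.
* **Class imbalance is left unweighted** in both boosting and the penalized
  fits.
* **Likert cutpoints** default to symmetric values on the log-relative-risk
  scale, keeping "no difference" centered at zero.
* **Survey item order** is randomized once per form under a recorded seed,
  not per respondent.
* **Noise-free panels and ranking.** With zero perception noise the panel is
  deterministic and unanimous, but the five-level Likert scale can tie rules
  whose external risks differ; the expert ranking is then consistent with
  the external-risk ranking in the sense of containing no strict inversion,
  which is the strongest property the coarsened scale admits.
* **Boosting defaults** (32 trees, 4 leaves, learning rate 0.1) put the
  candidate-rule count near one hundred under the default generator; tree
  count and depth beyond "shallow" are free parameters of the method.

## Problem sizes used by the test-suite experiments

The synthetic-generalization experiment runs the full pipeline on 50
independent seeds of the default generator (1000 internal + 250 external
intubations, ~10,000 windows) with a 25-expert panel at noise 0.25, and
compares the hard variant excluding 3 rules against the un-augmented
baseline on the external cohort. Bootstrap coverage is checked on a
binormal score model with known true AUC over 500 simulations of 150
observations with 400 bootstrap replicates each. The pipeline-level unit
tests use a miniature cohort (80 internal + 40 external intubations) so the
suite stays fast.

## Known limitations

* The generator's experts share a single scalar bias; systematically wrong
  expert consensus (the failure mode the method cannot fix) is representable
  only through that shift.
* The hard variant's exclusion count k must be chosen without an external
  validation set, mirroring the workflow's real constraint; the package
  reports all variants rather than selecting one.
* LASSO active sets are not globally monotone in lambda when rule columns
  are strongly correlated — the selected-rule count can shrink again as the
  penalty relaxes. This is a property of the L1 path itself, not of the
  implementation.
* With very small cohorts the panel simulator can produce unanimous (zero
  SD) responses for some rules; the SD floor keeps discordance finite but
  those rules' penalties then depend on the floor convention.
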