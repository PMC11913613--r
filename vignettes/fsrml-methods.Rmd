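---
title: "Feature self-recognition wrapper selection: models, assumptions, and design notes"
author: "fsrml package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature self-recognition wrapper selection: models, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fsrml)
```

## The problem

Pulmonary nodules — focal round lung opacities up to 3 cm on CT — are an
early potential sign of lung cancer, and screening programmes detect them in
large physical-examination populations. This package implements a
*feature self-recognition* modelling pipeline for tabular examination
cohorts: rather than pre-screening predictors, the full 33-column panel
(demographics, lifestyle, routine laboratory values) is handed to a wrapper
in which a swarm metaheuristic searches over binary feature masks and a
pluggable classifier scores each mask by cross-validated predictive
accuracy. The selected panel is then validated with conventional
epidemiological statistics (univariate chi-square / t tests, stepwise
multivariable logistic regression), and a trained model can be applied to
individual subjects as a low/high risk call.

## The optimizer

### Base algorithm

The sooty tern optimization algorithm (STOA) is a swarm method with two
phases. *Migration*: each candidate position $P$ is damped by a collision
avoidance factor $S_A$ that decays linearly from $C_f = 2$ to 0 over the
run ($C_{st} = S_A P$), and pulled toward the incumbent best
($M_{st} = C_B (P_{best} - P)$ with $C_B = 0.5\,\mathrm{rand}$), giving
$D_{st} = C_{st} + M_{st}$. *Attack*: the candidate spirals onto the best
position, $P \leftarrow D_{st}\,(x' + y' + z')\,P_{best}$, with
$x' = r\sin\theta$, $y' = r\cos\theta$, $z' = r\theta$ and the spiral
radius $r = u\,e^{-\theta v}$ at an angle $\theta \sim U(0, 2\pi)$ drawn
per candidate and per dimension.

Two numerical choices deserve a note:

* **Tightening spiral.** We parameterize the attack radius as decaying over
  the turn ($e^{-\theta v}$, a spiral that closes onto the prey). A widening
  radius ($e^{+\theta v}$) makes the attack factor span roughly $[1, 3900]$;
  multiplied into $D_{st} P_{best}$ every position explodes past the box
  bounds, all candidates clamp to corners, and the search cannot improve on
  its initial best — we verified this empirically on 2-D and 30-D test
  functions for additive and multiplicative placements alike. The tightening
  form reproduces the convergence behaviour this family of algorithms is
  known for, including its characteristic strength on origin-centred
  landscapes and weakness when the optimum sits far from the origin
  (e.g. Schwefel).
* **Component-wise draws.** $C_B$ and $\theta$ are drawn per candidate *and*
  per dimension, matching the base algorithm's nested-loop formulation.
  Per-candidate scalar draws couple all coordinates and destroy the
  component-wise contraction the update relies on.

Out-of-bounds components are clamped to the nearest bound (the simplest
feasibility-preserving rule; reflection would be an alternative). The
incumbent best is only ever replaced by an improvement, so the best-so-far
trace is non-increasing by construction for both variants.

### Improvements (ISTOA)

* **Bernoulli chaotic initialization.** The piecewise-linear Bernoulli
  shift $x_{n+1} = x_n/(1-\lambda)$ for $x_n < 1-\lambda$, else
  $(x_n - (1-\lambda))/\lambda$, with $\lambda = 0.4$, is ergodic on
  $(0,1)$ and spreads a small population more evenly than i.i.d. uniform
  draws. One continuing stream fills the whole position matrix; its
  starting value comes from the run's seeded generator, so a single seed
  reproduces the entire run. Finite-precision iterates that collide with a
  boundary point are re-injected into the open interval.
* **Cauchy mutation of the best.** With probability 0.5 per iteration
  (configurable; the probability is not fixed by the method's description,
  and 0.5 is the common choice in the Cauchy-perturbation literature) the
  incumbent best is perturbed multiplicatively,
  $X_{new} = X_{best} + X_{best} \odot c$, $c_j$ i.i.d. standard Cauchy.
  The heavy tails produce occasional large escape jumps; the zero vector is
  a fixed point of the multiplicative form. Acceptance is greedy.
* **Longitudinal–lateral (crisscross) crossover.** The method's description
  names the operator without formulas; we adopt the standard crisscross
  operators: lateral/horizontal crossover on shuffled pairs
  ($r x_i + (1-r) x_j + c\,(x_i - x_j)$, $r \sim U(0,1)$,
  $c \sim U(-1,1)$, per dimension) applied with probability 1.0 per pair,
  and vertical crossover mixing two random dimensions of one individual
  ($r x_{d_1} + (1-r) x_{d_2}$) with probability 0.6 per individual — the
  conventions of the crisscross-optimization literature. Offspring replace
  their parents only on improvement, preserving elitism.

Whether the Cauchy step should apply to all individuals or only the best is
not specified by the method's description; we perturb only the best, as the
update equation's $X_{best}$ suggests.

### Benchmarks

The 23 classical single-objective functions (Sphere through Shekel-10) are
the standard suite this literature compares on: F1–F7 unimodal scalable,
F8–F13 multimodal scalable (30-D by default), F14–F23 fixed-dimension
multimodal. The method's source does not enumerate its 23 functions; this
canonical suite is the only widely recognized 23-function set in the STOA
literature and matches the mix of 30-D and fixed-dimension landscapes shown
in its convergence figures, but it is a documented substitution, not a
confirmed match. F7's uniform $[0,1)$ observation noise is drawn from the
experiment's seeded stream so runs stay reproducible. Fixed-dimension
minima and optimizers are stored to ten significant digits, refined
numerically from the canonical formulas.

The packaged comparison (`run_benchmark_experiment()`) runs both variants
at population 30 for 500 iterations over ten seeds; the improved variant's
median final best is expected to be at least as good as the base variant's
on the large majority of the suite. Note the comparison is per-iteration,
not per-evaluation: ISTOA spends roughly three times as many objective
evaluations per iteration (crossover offspring and Cauchy proposals), which
is the convention the method's own comparison uses.

## The wrapper

Positions of dimension 33 live in $[-b, b]$ with $b = 4$ (the sigmoid
transfer is near-saturated beyond $\pm 4$, so a larger box only adds dead
space). Each position binarizes by $S(x) = 1/(1+e^{-x}) > 0.5$
(equivalently $x > 0$); an all-zero mask is repaired by forcing the largest
transfer value on, because an empty feature set is infeasible. The rule is
the most common wrapper-feature-selection convention; the mapping is not
fixed by the method's description, and a direct 0.5 cut on positions in
$[0,1]$ is available as an alternative.

The objective is $1 - \text{mean stratified 5-fold CV accuracy}$ of the
base classifier on the retained columns, evaluated on the training
partition only (the held-out 20% is never touched during the search).
Accuracy alone is the criterion; a sparsity weight is available but
defaults to 0. Fold assignment is a pure function of (labels, folds, seed),
and base-model fits run under an isolated RNG state, so the objective is
deterministic given its arguments, mask scores can be memoised, and the
reported best accuracy re-scores exactly. The inner objective uses
mean-of-folds accuracy; evaluation reports pool out-of-fold predictions
into one confusion matrix instead, because PR-AUC on small individual folds
is unstable. Both conventions are exposed.

Base models are deliberately library-default: logistic regression (IRLS),
rpart decision tree, k-nearest neighbours ($k = 5$, standardized inputs),
a single-hidden-layer feed-forward network (5 units, weight decay 0.01),
an RBF support vector machine, a 200-tree random forest, and gradient
boosting (60 rounds, depth 4, learning rate 0.3). Tuning base models is
out of scope; the wrapper's contribution is the mask search.

The 80/20 train/test split uses exact rounding — `round(n * fraction)` —
so a cohort of 4,861 splits into 3,889 and 972 — and is stratified by
label, as are the CV folds: the class balance (about 24% positive) is
preserved across partitions. Stratification is a documented tightening of
"random" splitting.

### What wrapper selection can and cannot do at n = 1,000

Cross-validated accuracy at $n = 1{,}000$ moves in steps of one
reclassified subject ($10^{-3}$), while a single irrelevant column changes
a regularized or margin-based learner's accuracy by less than that. Two
consequences, both visible in the package's own simulations:

* the choice of base learner shapes the landscape: for distance-based
  learners (KNN, RBF-SVM) every irrelevant column dilutes the metric, a
  real per-feature penalty — but the same dilution can make a *weakly*
  informative continuous column net-negative, so KNN reliably discards
  such features; for logistic regression weak informative columns always
  help, but single noise columns are nearly free and the objective's
  optima stay dense with fold-lucky noise;
* with fixed folds the search can exploit fold noise — retaining a noise
  column because it happens to help these folds. Selection frequencies
  across independently generated cohorts, not a single best mask, are the
  honest summary, which is what the recovery experiment reports;
* the limit is in the objective, not the search: in roughly a third of
  simulated cohorts at $n = 1{,}000$, dropping the weakest informative
  feature (standardized log-odds $\approx 0.5$) from the true mask does
  not reduce the CV-accuracy objective at all, so even an oracle optimizer
  of that objective would drop it. Averaged over seeds, informative
  features are still selected far more often than noise; a strict
  "every informative beats every noise" ordering of per-feature selection
  frequencies is not reliably attainable at this sample size.

The packaged recovery experiment uses the logistic-regression wrapper with
the fixed-0.5-cut encoding on unit-box positions — under which the
optimizer's origin contraction doubles as parsimony pressure — and a
sparsity weight of $5 \times 10^{-4}$, deliberately below one reclassified
subject ($10^{-3}$) in total, so it is strictly lexicographic: it can only
break exact accuracy ties toward the smaller mask, never trade accuracy
away.

## Cohort statistics

Univariate screening uses the Pearson chi-square **without** continuity
correction for binary features and the pooled-variance (Student) two-sample
t for continuous ones — the SPSS-style conventions for large-cohort
univariate tables; both reproduce printed cohort statistics from published
count tables and (mean, sd, n) summaries to three decimals, which Yates
correction and Welch t do not. Both tests are exposed directly from
summary-level inputs, so published tables can be recomputed without
subject-level data.

Stepwise logistic regression is forward-by-Wald-p (entry 0.05) with
backward removal (0.10), the SPSS defaults; fits are ordinary
maximum-likelihood IRLS, and the final table reports
$\beta$, SE, Wald $= (\beta/\mathrm{SE})^2$, $p$,
$\mathrm{EXP}(B) = e^\beta$ and the log-symmetric CI
$e^{\beta \pm 1.96\,\mathrm{SE}}$. Arithmetically symmetric CIs around
$\mathrm{EXP}(B)$ sometimes seen in print are inconsistent with the
logistic model's sampling theory; the package emits only the standard
log-symmetric form. Under 33 pure-noise candidates, forward entry at 0.05
admits a small number of false positives by multiple testing
(binomially $\approx 33 \times 0.05$ expected below the entry threshold),
so a "near-empty" null model means a handful of features, not strictly
zero — the package's null simulations define near-empty as at most 10% of
candidates.

## The synthetic cohort generator

No subject-level data ships with the package; a seeded generator emulates
the study conditions so every pipeline stage is testable.

* **Schema.** 33 predictors: 11 binary and 22 continuous (demographics,
  lifestyle, and a routine laboratory panel), plus a binary `nodule` label
  at prevalence $1168/4861 \approx 0.2403$ and default size $n = 4861$.
  The published univariate table treats elevated carcinoembryonic antigen
  as a yes/no indicator with class prevalences but never states the
  cut-off, so the generator produces the indicator directly rather than a
  raw marker. The recorded panel enumerations are internally inconsistent
  about occupational exposure (air pollution at the workplace) versus place
  of residence; the schema keeps `occupational_exposure` — the variable the
  risk analyses actually use — as the environmental-exposure item.
* **Class-conditional generator** (`generate_cohort()`): labels are
  Bernoulli(prevalence); within class, the eight informative features (age,
  smoking, psychological stress, occupational exposure, chronic lung
  disease, family history of lung cancer, albumin, elevated CEA) follow
  their published class-conditional marginals (e.g. smoking 39.78% in
  negatives vs 69.78% in positives; age $33.87 \pm 8.43$ vs
  $43.32 \pm 9.16$ years); the other 25 features follow reference-interval
  placeholder marginals with **no** group contrast. This generator feeds
  the univariate-statistics tests: calibrated contrasts must flag, pure
  placeholders must reject at the nominal 5% rate.
* **Logistic-link generator** (`generate_logistic_cohort()`): predictors
  come from their pooled marginals; the label follows
  $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \beta^\top z))$ over
  predictors standardized by their *theoretical* pooled moments, so the
  generating coefficients are exact ground truth, recorded in the cohort
  metadata for recovery tests. Default standardized log-odds use the
  published multivariable coefficients where printed (age 1.536, smoking
  1.231, stress 0.515, occupational exposure 1.067, chronic lung disease
  0.742, elevated CEA 1.011) and moderate placeholders for the two
  wrapper-selected features absent from that table (family history 0.7,
  albumin $-0.5$, negative because albumin is lower in positives). The
  intercept $-2.3$ puts prevalence near the cohort's 0.24.

Features are generated independently (no covariance information is
published); real laboratory panels are correlated, continuous marginals are
truly skewed rather than normal, and real cohorts contain missingness —
none of which the generator emulates. Passing recovery tests therefore
demonstrates that the machinery identifies conditionally informative
features under the stated model, not that it would produce the same panel
on real hospital data.

## Problem sizes used by the packaged experiments

The packaged acceptance experiments run at the study's stated scales where
one is stated: the optimizer comparison at population 30, 500 iterations,
10 seeds over all 23 functions; wrapper recovery on five independent
logistic-link cohorts of $n = 1{,}000$ (logistic-regression wrapper,
fixed-cut encoding, population 30, 300 iterations — sized so the mask
search converges past its dense local optima); univariate type-I
calibration over 200 cohorts of $n = 1{,}000$;
logistic recovery at $n = 5{,}000$. The worked examples in the README use
smaller sizes chosen only for illustration.

## Known limitations

* The base optimizer inherits the family's origin bias: multiplicative
  attack steps contract toward the coordinate origin, flattering results on
  origin-centred benchmarks. The improved variant's crossover compensates
  on shifted optima but does not remove the bias.
* Wrapper accuracy differences at moderate $n$ sit near the resolution of
  cross-validation, so selected masks legitimately vary across seeds;
  report selection frequencies, not a single mask.
* The stepwise table's Wald inference ignores the selection process, as
  stepwise inference always does; treat its p-values as descriptive.
* The CLI's risk threshold (default 0.5) dichotomizes a probability; it is
  a reporting convention, not a clinically calibrated operating point.
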