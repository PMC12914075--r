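---
title: "Methods: from protein panels to mediated treatment effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from protein panels to mediated treatment effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picpmed)
```

## The scientific problem

Mineralocorticoid receptor antagonists such as spironolactone lower serum
PICP (procollagen type I C-terminal propeptide), a circulating marker of
collagen type I synthesis and, indirectly, of fibrotic activity. The
question this package addresses is *through which circulating proteins*
such a treatment effect is transmitted. The workflow couples a
longitudinal Olink-style NPX protein panel (log2-scale relative
abundances, three visits) to a serum outcome, and proceeds in stages:

1. **Feature construction** — per protein, a baseline feature and a
   fold-change feature (`2^(NPX_final - NPX_baseline)`); the outcome is
   its concentration fold-change (final/baseline). Features are min-max
   rescaled to [0, 1] with scaling fitted on the training partition only.
2. **Consensus selection** — four regression learners (elastic net,
   random forest, gradient boosting, a small feed-forward network) are
   tuned by 3-fold cross-validated grid search on an 80/20
   arm-and-outcome-quartile-stratified split, and ranked by permutation
   importance. Within each timepoint, features in the top 10% of at
   least two learners are kept; features surviving at both follow-up
   visits form the final set.
3. **Mediation** — candidate mediators are screened (treatment effect on
   the protein change, and treatment x protein interaction on the
   outcome), combined into a *signature score* (OLS of the outcome
   fold-change on all candidate fold-changes), and the score is analysed
   as a single composite mediator.
4. **Trajectories and trends** — subject-specific slopes from
   random-intercept/random-slope mixed models, slope-on-slope OLS with an
   omnibus F-test and robust refit; quartile trend tests
   (Spearman / Cochran-Armitage) and median-stratified treatment effects.
5. **Enrichment** — hypergeometric over-representation of the selected
   proteins against user-supplied GMT term sets, under a genome-style or
   panel background.

Individual-level data from the motivating trials are not publicly
deposited, so the package ships a synthetic trial generator with known
causal ground truth; every stage is validated against that truth.

## The mediation model

With binary randomized treatment $A$, composite mediator score $M$,
outcome fold-change $Y$ and pretreatment covariates $X$ (baseline outcome
and baseline mediator values), two linear models are fitted:

$$M = \alpha_0 + \alpha_1 A + \alpha_X X + \varepsilon_M, \qquad
  Y = \beta_0 + \beta_1 A + \beta_2 M + \beta_X X + \varepsilon_Y.$$

The average causal mediation effect is $\mathrm{ACME} = \alpha_1\beta_2$,
the average direct effect $\mathrm{ADE} = \beta_1$, the total effect
$\mathrm{TE} = \mathrm{ACME} + \mathrm{ADE}$ (exact for this
no-interaction linear estimator, asserted to 1e-10), and the mediated
proportion $\mathrm{ACME}/\mathrm{TE}$. Interval estimation is a
nonparametric bootstrap over subjects with percentile intervals
(default 1000 resamples). The same ACME is obtained by explicit
counterfactual prediction $E[Y(1, M(1))] - E[Y(1, M(0))]$ from the two
fitted models; `acme_counterfactual()` keeps that second code path as an
internal oracle and the equality is asserted to machine precision in the
test suite.

**Leave-one-out mediated-proportion loss.** The contribution of mediator
$j$ is the drop in mediated proportion when the signature score is refit
without $j$ and the mediation rerun. Within each bootstrap replicate the
same subject resample is used for the full and all reduced models, so
each loss is a paired difference (variance reduction); score weights are
refit on every resample. Two caveats are demonstrated in the tests: a
mediator with no causal role has loss near zero, and two duplicated
mediators mask each other (each has loss near zero although they mediate
jointly) — losses quantify *unique* contributions.

**Analysis scale.** The mediated proportion is scale-dependent. The
generator's structural equations are exactly linear on the *log* outcome
fold-change scale, so the package's validation analyses use
`log(fold-change)` as the outcome; the raw ratio scale is available in
every exported table for sensitivity analyses. When the proportion's
numerator and denominator have opposite signs, or |TE| is below
tolerance, the result carries an `unstable` flag rather than being
suppressed.

## The synthetic trial generator

`sim_config()` / `simulate_trial()` encode a linear structural equation
model: per-protein baseline NPX is Gaussian; mediator proteins change by
$a_j A$ (log2 NPX units) plus covariate terms and noise; the log outcome
fold-change is $c A + \sum_j b_j \Delta_j$ plus covariate terms and
noise. Ground truth is closed form: ACME $= \sum_j a_j b_j$, ADE $= c$,
TE their sum. Defaults mirror the motivating trial's shape: 488 subjects
randomized 1:1, 276 proteins, visits at 0, 1 and 9 months, eight
mediators whose coefficient products give a true mediated proportion of
0.699 (matching the order of the reported early-visit value), persistent
effects at the late visit (`visit2_decay = 1`). Age, sex and eGFR enter
both the mediator and the outcome equations so that covariate adjustment
is non-trivial. Designated proteins additionally carry subject-specific
random slopes (SD 0.04 NPX/month), and echocardiographic variables
(LAVI, E:A ratio) have slopes generated as linear combinations of those
protein slopes plus noise — the ground truth for the trajectory stage.

What the generator does *not* emulate: the empirical correlation
structure of a real Olink panel (proteins are independent given the
mediator structure), assay floor effects, missing visits, or informative
dropout. Passing the recovery suites therefore shows the estimators are
correct under the assumed model, not that the pipeline is robust to
those real-data complications.

Noise levels were chosen once so that the outcome fold-change spread is
of the magnitude reported for such trials (log fold-change noise SD
0.12, giving quartile cut-points a few tenths either side of 1), and
the NPX change noise SD (0.35) gives per-protein fold-change spreads
typical of plasma panels; `analysis/01_simulate.R` prints the realized
cut-points for the default configuration.

## Learners, importance, and the consensus rule

Hyperparameter grids are deliberately small and config-exposed (the
original tuning grids are not public): elastic net over mixing and
penalty; random forest over `mtry`; gradient boosting over depth, rate
and rounds; the network over width, weight decay and epochs. Grid points
that fail to converge score +Inf and are logged, never fatal. A constant
training target short-circuits to an intercept-only predictor.

Permutation importance is the mean increase in RMSE over `n_perm`
independent shuffles of one feature column. The definition is evaluated
exactly; for speed the implementation recomputes predictions
algebraically from the fitted weights (linear, network) or re-traverses
only the trees that split on the shuffled feature (forests, boosting),
and each such path is verified against the model's own `predict` on the
unshuffled data with a fallback to plain batched prediction. Negative
importances are reported as computed.

Two defaults deserve note. First, importance is evaluated on the
training partition by default (`importance_on = "train"`), with the
held-out partition available as a flag; the package's own recovery
analyses use the held-out partition because the evaluation there is not
inflated by fit to the training noise, and it is four times cheaper at
the stated problem sizes. Second, the 10% threshold applies to the full
predictor roster (proteins and clinical features alike), since clinical
features compete for the same decile in the original design.

The recovery analysis shipped in the tests plants 5 mediators among 100
noise proteins at n = 500 with 200 permutations; on the
outcome-correlation scale each planted mediator contributes 0.32-0.39
SD, i.e. moderate effects. Recovery requires every planted mediator's
fold-change feature to appear in the cross-timepoint consensus in at
least 18 of 20 seeds. These problem sizes (and the single-point grids
used there) are the package's validation conditions; the grid-search
machinery itself is exercised separately.

## Trajectory models

`fit_random_slopes()` fits `value ~ time + (time | subject)` by REML
(lme4), with time in months (0, 1, 9 by default) and slopes per month. A
singular random-effects covariance falls back to independent random
effects, and a complete lmer failure to a documented two-stage
fallback (per-subject OLS slopes with empirical-Bayes shrinkage). The
returned slope is fixed effect + BLUP; shrinkage relative to per-subject
OLS is a tested property, as is convergence to per-subject OLS as the
residual SD goes to 0.

`regress_slopes()` regresses an outcome slope on two protein slopes,
adjusted for age, sex, arm and eGFR; the omnibus p is the joint F-test of
the two slope terms against the covariate-only model; the prediction
surface holds covariates at sample means. Model-adequacy diagnostics
(residual summary, Shapiro-Wilk statistic, maximum Cook's distance)
accompany every fit. The robust refit is always computed — an
M-estimator with Tukey's bisquare loss — and a divergence flag marks
coefficients that moved by more than one OLS standard error, rather than
applying a subjective "when necessary" trigger.

## Trend and stratification statistics

Continuous variables use Spearman rank correlation against the quartile
index 1-4 (two-sided, t approximation since ties preclude the exact
null). Binary variables use the Cochran-Armitage trend score test with
equally spaced scores 1..k by default (alternative scores are an
argument); the statistic's square equals the classical chi-squared trend
statistic, and the signed Z retains direction. Quartile assignment ranks
subjects ascending and allocates remainder subjects to the lowest groups
first — the unique convention reproducing group sizes 121/120/120/120 at
n = 481 — with ties broken by stable input order. Trend p-values in the
summary table are reported unadjusted (matching the field's Table-1
convention) with a Benjamini-Hochberg column alongside.

Median stratification splits at "baseline value > median"; with an even
sample and distinct values this gives two equal strata. The stratum
effect is the covariate-adjusted arm coefficient; heterogeneity is the
arm x stratum interaction p from the pooled model.

## Enrichment

`ora()` computes the upper-tail hypergeometric probability of observing
at least k query hits per term (equivalently one-sided Fisher), BH
adjustment applied once across tested terms, fold-enrichment
`(k/n)/(K/N)`. Two background modes mirror the two sensitivity analyses:
a genome-style symbol list or the measured panel itself. Two filter
conventions: `adjusted` (p < 0.05 and q < 0.05) and `fold`
(fold-enrichment > 5 with unadjusted p < 0.05, the convention that
remains usable under the small panel background). Annotations come from
GMT files; symbol matching is exact after case-folding, and unmatched
query symbols are reported, never silently dropped. Because term content
depends on annotation release, enrichment outputs are structural and
never value-anchored in the tests.

## Numerical and degenerate-input choices

- Quartile ties: stable input order (a convention; the original
  analysis's tie rule is unknown).
- Fold-changes over a zero baseline (possible for score-like clinical
  variables) become missing, and all feature-matrix rows are
  complete-case filtered with counts logged.
- Zero-variance feature columns scale to constant 0 with a warning;
  zero-variance proteins are skipped in screening with a logged reason.
- Exact collinearity in the signature score drops the offending column
  (reported); p >= n is refused.
- |TE| < 1e-8 flags the mediated proportion as unstable.
- All stochastic stages (split, CV folds, permutations, bootstrap,
  generator) take explicit seeds and restore the caller's RNG state.

## Validation problem sizes

The shipped test suite runs the mediation coverage study at n = 1000
with 1000 bootstrap resamples over 100 seeded replications; LOO ranking
at n = 800 (5 mediators + 50 noise proteins, 20 seeds); consensus
recovery at n = 500 (105 proteins, 200 permutations, 20 seeds);
calibration suites at 150-500 replications. These sizes were chosen as
the smallest at which the stated recovery thresholds are comfortably
identifiable; all are config arguments, so larger studies are one-line
changes.

## Known limitations

- The consensus stage's statistical behaviour is characterised under
  independent proteins; correlated blocks (configurable in principle)
  will split importance across correlated features, as the duplicated
  column tests demonstrate.
- The mediated proportion inherits all caveats of mediation analysis:
  sequential ignorability is assumed, not tested (no sensitivity
  analysis is provided, matching the scope of the original analysis).
- The signature score reuses the analysis sample to estimate its
  weights; with many weak candidates at modest n this inflates the
  apparent mediated proportion, which is why the validation anchors on
  configurations whose truth is known.
- The network learner is a single-hidden-layer regressor; it stands in
  for "a small feed-forward network", not for any particular deep
  architecture.
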