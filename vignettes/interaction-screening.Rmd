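---
title: "Screening gene-gene interactions in high-dimensional survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene-gene interactions in high-dimensional survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular studies with time-to-event endpoints routinely measure hundreds
to thousands of covariates (gene expression features) on some 100-300
subjects. Main-effect variable selection in the Cox proportional hazards
model is well served by sparse methods, but *two-way interactions* --
effects of products $x_a x_b$ on the log hazard -- are much harder: with
$p$ covariates there are $\binom{p}{2}$ candidate products, and the
interactions of greatest biological interest are precisely those whose
component variables carry no main effect and therefore leave no marginal
trace for a linear selector to find.

`survscreen` implements a screening pipeline that combines four building
blocks:

1. **Componentwise likelihood-based Cox boosting** for sparse model
   fitting (main-effect detection and the final model);
2. **Random survival forests with permutation importance** to pre-select
   candidate pairs: a pair is deemed relevant in a resample when *both*
   variables have positive permutation importance in the same forest;
3. **Orthogonalization**: before the forest step, all covariates outside
   the detected main-effect set are replaced by their least-squares
   residuals on the detected main effects, unmasking interaction signal
   that would otherwise be absorbed by correlated main effects;
4. **Subsampling** (0.632 without replacement) both around the whole
   pipeline (honest prediction error) and inside the pre-selection step
   (inclusion-frequency stability).

## Models and estimators

### Componentwise boosting for the Cox model

The Cox model $\lambda(t \mid x) = \lambda_0(t) e^{x'\beta}$ is fit by
maximizing the Breslow partial log-likelihood
$$\mathrm{PLL}(\beta) = \sum_i \delta_i \Big\{ x_i'\beta - \log
\sum_j I(t_i \le t_j)\, e^{x_j'\beta} \Big\}.$$
Starting from $\beta^{(0)} = 0$, each boosting step evaluates, for every
penalized covariate $j$, the score $U_j$ and Fisher information $I_j$ of
the one-parameter direction $\theta_j$ at $\theta_j = 0$, forms the
penalized score statistic $U_j^2 / (I_j + \rho)$, and updates the
maximizing covariate by $\hat\theta_{j^*} = U_{j^*} / (I_{j^*} + \rho)$.
The penalty $\rho = (\sum_i \delta_i)(1/\nu - 1)$ turns $\nu$ into a
relative step size; the package default $\nu = 0.05$ gives updates about
5% of a Newton step. Mandatory (clinical) covariates receive an
unpenalized componentwise update at the start of every step. Covariates
are standardized internally (so score statistics are comparable across
columns) and the scaling is stored with the model; predictions accept
covariates on their original scale.

The number of boosting steps is the one genuinely free tuning parameter.
It is selected by 10-fold cross-validation of the Verweij-van Houwelingen
predictive partial likelihood (full-data PLL at the fold coefficients
minus training-fold PLL), with folds stratified by event status and a
search cap of `max_steps = 100`.

### Random survival forests

Trees are grown unpruned on per-tree 0.632 subsamples drawn without
replacement. At each node, `mtry` (default $\approx \sqrt{p}$) candidate
covariates are drawn; every midpoint between adjacent distinct in-node
values is a candidate threshold, scored by the standardized two-sample
log-rank statistic between the daughters; the best split wins. A node
with fewer than three distinct event times becomes a terminal node
carrying the Nelson-Aalen cumulative hazard
$\hat H_h(t) = \sum_{l: t_{l,h} \le t} d_{l,h} / Y_{l,h}$ of its cases.
A case's *ensemble mortality* is the mean terminal cumulative hazard over
trees, summed over the grid of training event times -- higher mortality,
higher predicted risk.

Permutation importance of covariate $j$ permutes the column (seeded),
recomputes out-of-bag ensemble mortality and reports the increase in
$1 - C$, where $C$ is Harrell's concordance. A covariate never used by
any tree has importance exactly zero; on noise data importances scatter
around zero with many non-positive values.

### Prediction error

Prediction accuracy is tracked by the expected Brier score over time,
$\widehat{\mathrm{Err}}(t) = n^{-1} \sum_i W_i(t) \{\delta_i(t) -
\hat\pi(t,x_i)\}^2$, with $\hat\pi(t,x) = 1 - e^{-\hat H_0(t) e^{x'\beta}}$
the predicted event probability and IPCW weights
$W_i(t) = I(t_i \le t)\delta_i / \hat P(t_i-) + I(t_i > t) / \hat P(t)$
built from the reverse Kaplan-Meier estimate $\hat P$ of the censoring
distribution (estimated on the training part; cases censored before $t$
get weight zero). Curves are integrated trapezoidally (IPEC) and reported
relative to the Kaplan-Meier reference:
$\mathrm{rIPEC} = (\mathrm{IPEC}_{KM} - \mathrm{IPEC}_S) /
\mathrm{IPEC}_{KM}$.

## The assembled strategies

`run_strategy()` executes, for one master seed: an outer 0.632 split into
$Z_b$ / $Z_b'$; first-pass main-effect detection ("CoxBoostM") giving the
index set $M$; strategy-specific pair pre-selection; a final boosted Cox
fit over $\{$mandatory$\} \cup M \cup \{$products of selected pairs$\}$,
where products are always built from the *original* (non-residualized)
covariates; and the IPCW Brier curve of the final model on $Z_b'$.

The four strategies differ in the pre-selection step:

| name | pre-selection |
|------|---------------|
| `rsf-VIF-res` | orthogonalize against $M \cup K$, then $S$ inner subsamples, forest + importance, pairs of jointly positive-importance covariates ranked by inclusion frequency |
| `rsf-VIF` | the same without orthogonalization |
| `cb-VIF` | boosted Cox on $S$ inner subsamples; pairs ranked by min of the two per-variable inclusion frequencies (ties: larger sum, then lexicographic) |
| `cb-crossp` | all $\binom{|M|}{2}$ cross products of the detected main effects (a seeded uniform subset of $R$ if more) |

Ties at rank $R$ of the pre-selection ranking are always included, so the
returned list can exceed $R$.

## Design choices in genuinely open places

* **Step number as a per-dataset setting.** The boosting step number for
  first-pass main-effect detection is cross-validated once on the full
  dataset and shared by fits on its subsamples, rather than re-run per
  subsample. The cross-validated objective on a 95-subject subsample of
  these designs is nearly flat, and its argmax is both noisy and
  systematically smaller than the step count the full dataset supports;
  treating the step number like the penalty -- a dataset-level setting --
  gives first-pass models whose size and main-effect sensitivity are
  stable across subsamples. The final model's step count is
  cross-validated on its own candidate design.
* **Two selection modes.** `run_strategy(selection = "subsample")` fits
  the selection steps on the training part of the outer split -- the mode
  for stability analyses on real data, where inclusion frequencies across
  many outer splits are the quantity of interest; each boosted fit there
  cross-validates its own step count on its own design.
  `selection = "full"` fits selection on all rows (maximal power, the
  natural mode when each simulated dataset is analyzed once), treats the
  cross-validated step number as a per-dataset setting shared by every
  boosted fit -- first pass, inner inclusion-frequency fits and final
  model alike -- and uses the split only to track prediction error; its
  Brier curves are then partly in-sample and read as relative
  comparisons between models, not as honest absolute error.
  `reproduce-table` and the acceptance script use the full mode.
* **Subsampling without replacement** at relation 0.632 everywhere
  (outer split, inner pre-selection subsamples, per-tree resamples); a
  training part without events is redrawn (up to 100 times) with an
  incremented seed.
* **Ties**: Breslow convention in all partial-likelihood quantities; the
  matching Breslow estimator for the cumulative baseline hazard.
* **Marginal censoring model**: the IPCW weights use the covariate-free
  reverse Kaplan-Meier; covariate-conditional censoring models are out of
  scope.
* **Evaluation grid**: distinct event times of the test part, truncated
  where the censoring survival drops to 0.05, for weight stability.
* **Degenerate chains**: when no candidate covariate at all reaches the
  final model, the pipeline reports the Kaplan-Meier reference itself
  (rIPEC exactly 0) rather than a null Cox fit.
* **Constant columns** cannot be standardized; their scale is recorded
  as 1 and a warning emitted.

## The simulation engine

`builtin_scenarios()` returns the twelve study arms: `Sim42` (four main
effects $3, 3, -3, -3$; interactions $5, -5$ *on* the main-effect pairs),
the `Sim22_x` family (mains $0.9, -0.9$; interactions $\pm x$ on four
variables with no main effect), `Sim22_bin` (those four variables
Bernoulli(1/2)), and `Sim22_corr01..07` (all covariates in 5-variable
blocks with within-block correlation 0.1-0.7; every true variable in a
distinct block). Defaults $n = 150$, $p = 1000$. Event times are
exponential with rate $\lambda e^{\eta}$, $\lambda = 1/20$; censoring
times are exponential with the same baseline rate, independent of
everything, giving the roughly 50% censoring typical of oncology cohorts.
Binary covariates are coded $\{0, 1\}$.

What the generator does *not* emulate: measurement error and
normalization artifacts of real expression data, non-proportional or
time-varying effects, informative censoring, and heavy-tailed covariate
distributions. Passing tests on these scenarios therefore show that the
pipeline recovers multiplicative log-hazard interactions under the stated
design, not that it is robust to those departures.

## Problem sizes used by the test-suite

The study's headline numbers are means over 50 replicate datasets of a
pipeline with $S = 50$ inner subsamples and 1000-tree forests -- a
cluster-sized computation. The package's own checks run the same code at
reduced scale, chosen once: the boosting-only strategy (`cb-crossp`) at
$p = 300$ with 15 replicates and 5 CV folds (the acceptance script runs
it at the full $p = 1000$), and the forest-based strategies at
$p = 200$, $S = 10$, 250-tree forests, $R = 10000$ (the default) and 4-5
replicates. One caveat of reduced dimension: screening-scarcity effects
that depend on $p = 1000$ -- a candidate pair competing with half a
million others for the inclusion-frequency ranking -- saturate at
$p = 200$, so reduced-scale interaction sensitivities of the forest
strategies sit above their full-scale counterparts. The remaining
qualitative contrasts (orthogonalized forest screening finds
interactions that cross products of main effects cannot; correlation
collapses main-effect recovery; small interaction effects are screened
but not selected) are all visible at these sizes, while a full run
remains a scripted reproduction (`scripts/acceptance.R` plus
`reproduce-table`) rather than a unit test.

## Known limitations

* Only two-way multiplicative interactions are screened; higher-order or
  non-multiplicative structure is out of scope.
* The common (column-permutation) importance is implemented; the
  tree-path randomization variant specific to survival forests is not.
* No competing risks, left truncation, interval censoring or missing
  data.
* The cb-VIF pair ranking from per-variable frequencies is one of several
  defensible conventions (min, then sum, then lexicographic); it is
  chosen for determinism and symmetry.
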