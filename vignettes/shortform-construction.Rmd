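---
title: "Short-form construction by cross-validated Shapley rankings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-form construction by cross-validated Shapley rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfirank)
```

## Overview

`sfirank` reduces a 61-item suicide-risk scale to a short form by ranking
items on their predictive contribution to binary screener outcomes. The
procedure is stability selection in spirit: rather than trusting one
model's coefficients, it repeats stratified K-fold cross-validation R times
and counts, per item, the fold-models in which that item's global Shapley
importance lands in the top k. That count — SFI, the SHAP Feature
Importance — is robust to fold-to-fold noise in a way single-fit
importances are not, and it is what the ranking, comparison and assembly
stages consume.

This vignette records the model and its assumptions, the tunable
parameters, what the synthetic cohort emulates (and what it does not), the
numerical choices, and the places where the design was genuinely open.

## The estimator

The implemented classifier is logistic regression fit by Newton/IRLS on
standardized features with a ridge penalty (`l2_penalty`, default 1.0 on
the standardized scale, the conventional weak default; the penalty never
touches the intercept). Convergence requires the maximum absolute
penalized score below 1e-8 (or stops with an error after 100 iterations).
Unpenalized fits detect perfect separation — all fitted probabilities
numerically 0 or 1 — and error with a suggestion to add penalty rather
than report unbounded coefficients. Tree ensembles can be plugged in
behind the same fit/predict contract; they are deliberately not shipped,
since the linear model is both the strongest performer for this problem
class and the one with a closed-form Shapley solution.

Performance indices are computed from their definitions: confusion-matrix
metrics at a probability threshold (default 0.5 — the choice is
configurable because the original analysis does not state one), AUROC via
the Mann–Whitney rank formulation with half credit for ties, and AUPRC as
step-wise average precision. Average precision (not trapezoidal
interpolation) matters under the ~2% prevalence of the SI-P outcome, where
interpolation is optimistically biased.

## Shapley attribution

Attributions are computed on the **margin (log-odds) scale**, where
additivity is exact: for every row, `base_value + sum(phi) = margin`, to
1e-8 or better. Probability-scale attributions would not sum to the
prediction and are not offered.

Three routes are implemented and cross-checked against each other:

* **Exact enumeration** over all 2^p coalitions (p ≤ 14), the oracle.
  The coalition value is interventional: out-of-coalition features are
  replaced by background values (independent-features convention — the
  same convention the usual linear explainer applies to logistic models).
* **Linear SHAP**, the closed form `phi_ij = beta_j (z_ij - z_bg_j)`, used
  in production. It equals the oracle to 1e-10 on linear models.
* **Kernel SHAP**, weighted least squares over coalition indicators with
  the Shapley kernel `(p-1)/(C(p,k) k (p-k))` and efficiency enforced by
  elimination; full enumeration when 2^p ≤ 2^14, otherwise
  kernel-weighted coalition sampling under a fixed seed.

Global importance is the mean **absolute** attribution over evaluation
rows. The source procedure states only that contributions are averaged;
signed means cancel for symmetric effects and cannot produce a meaningful
ranking, so the mean-|phi| summary convention is adopted (the signed mean
is available as an option).

Background/reference: the training-fold feature means (a single synthetic
reference row) for linear SHAP; any background sample for kernel SHAP.

## The SFI loop

Per repetition, classes are shuffled independently and dealt round-robin
to K folds, so per-class fold sizes differ by at most one — the stratified
scheme the severe SI-P imbalance requires (a minority class smaller than K
is an explicit error). Each fold-model is fit on the out-of-fold rows;
attributions are computed on the **held-out** fold (so importance reflects
generalization, not fit; training-fold attribution is available via
`shap_rows`), and the top-k items by importance are stored, ties broken by
bank order.

Two bookkeeping decisions deserve note:

* **The SFI ceiling is R·K, not R.** Counting per fold-model (4000 at the
  defaults) is the only reading consistent with the statistic's published
  maximal values; the package counts that way and documents it.
* **Failed fold-models** (degenerate single-class training rows, possible
  under extreme imbalance) are dropped with a warning and a logged count
  rather than aborting a 4000-fit run; the ceiling shrinks accordingly.

Whenever p > k the conservation identity `sum(SFI) = k × n_fold_models` is
asserted on every run. Reproducibility: repetition r derives its fold seed
as `seed + r`; identical configurations give identical rankings.

## Comparison and assembly

Rankings are compared to an 8-item reference short form by **criterion
distribution**: the proportion of a list's items per SCS criterion. The
comparison depth defaults to the top 10 because SFI values typically drop
below half their starting value past the 10th position. The published
comparison is visual; it is formalized here as
`similarity = 1 - 0.5 * L1(p, q)` between criterion proportion vectors —
bounded in [0, 1], symmetric, 1 iff the distributions coincide. Any
bounded scalarization would serve; this one is interpretable as shared
probability mass.

Assembly takes, per criterion, its quota of highest-ranked items from the
primary ranking (quota default `{A:2, B1:2, B2:2, B3:2, B4:1}`, nine
items); a criterion the primary ranking cannot fill falls back to the
second ranking, with the source recorded per pick. "Top-ranking item of a
criterion" is resolved by rank order, so ties inherit the ranking's
stable-bank-order tie rule. Quotas are exact: a shortfall is an error,
never a silently smaller form.

The source description is contradictory about which outcome seeds the
final form (the methods text says the preparatory-behavior ranking with an
ideation-ranking fallback for social withdrawal; the abstract and the
final item table say the ideation ranking). `assemble_short_form()` is
therefore parameterized over primary/fallback; the pipeline default uses
the SI ranking as primary, which reproduces the published nine-item
composition, and the alternative reading is one argument swap away.

## The synthetic cohort: what it emulates

No study data are available, so validation runs on simulated cohorts
designed to match the *stated* statistical structure:

* five correlated latent factors (the SCS criteria);
* 61 ordinal items generated by a multidimensional graded-response
  (ordinal probit) mechanism: item propensity = loadings · factors + unit
  normal noise, cut at four ordered thresholds;
* binary outcomes logistic in the latent factors — not in the item
  responses — so measurement noise attenuates prediction realistically;
  intercepts calibrated by monotone bisection to hit target prevalences to
  1e-6 (SI 19.11%; SI-P 241/10357 ≈ 2.33% — the source's printed 2.23%
  conflicts with its own case counts, and the generator follows the
  counts);
* outcome coefficients weighting entrapment highest (≈2.5× the other
  factors), consistent with entrapment being the syndrome's core
  component.

**Calibration.** Own-criterion loadings are 1.3 (communality ≈ 0.63),
inter-factor correlation 0.8, thresholds (−0.5, 0.35, 1.2, 2.0) in
latent-SD units. These were chosen once, before any acceptance test was
written, to jointly reproduce (i) total-score reliability α ≈ .98 on 61
five-category items and (ii) a right-skewed community-sample response
distribution (mean response ≈ 1.2 on 0–4). Weaker nominal values
(loadings ≈ 0.75, correlations 0.6) are *provably incompatible* with
α = .98 under unit residual noise — they cap α near 0.94 — so reliability,
being the instrument's one published moment, won. With this calibration,
simulated α is 0.982 stably across seeds, and held-out AUROC for SI lands
near 0.81–0.84 — the plausible regime for this problem, though no
real-data index is treated as a target.

**What a green test does not establish.** The generator draws factors
multivariate-normal with equicorrelated structure, items with simple
structure (no cross-loadings), no differential item functioning, no
country or demographic heterogeneity, no missingness mechanism, and
outcomes that depend on the factors only. Recovery results (entrapment
items topping the ranking when only the entrapment factor carries outcome
signal) therefore validate the *machinery* — fold logic, attribution,
aggregation, tie handling — not the substantive claim that any particular
real item belongs in a short form.

## Numerical choices and degenerate inputs

* Likert entries outside 0–4, non-binary screener entries, duplicate item
  ids, and unknown criterion tokens are validation errors; a bank not
  covering all five criteria is accepted with an explicit warning flag.
* Reverse-coded items map x → 4 − x; the response matrix records that the
  map has been applied and refuses a second application (which would
  silently undo the first). The generator emits severity-coded responses
  directly.
* Missing responses: complete-case deletion at the respondent level, with
  the dropped count reported — the simplest defensible rule absent any
  statement about missingness.
* Ties: everywhere (top-k boundary, final ranking, assembly) broken by
  stable bank order, documented in the outputs.
* Constant features: standardized with scale 1 so a penalized fit shrinks
  their coefficient to zero instead of erroring mid-loop.
* All randomness flows from explicit integer seeds; samplers
  save and restore the global RNG state so library calls never perturb a
  caller's stream.

## Limitations

* Only the linear-model attribution path is production-grade;
  tree-specific Shapley algorithms are out of scope.
* Kernel SHAP's sampling branch (p > 14) is importance-sampled and
  stochastic; for the 61-item instrument the linear route is always used.
* The full-scale default (n ≈ 10⁴, p = 61, R = 1000, K = 4) runs in
  roughly 5–10 minutes on one CPU in pure R (measured: R = 50 at
  n = 10,357 in ~17 s, extrapolating to ~6 min); the test suite exercises
  the identical code path at R = 50 and extrapolates.
* The similarity scalar compares criterion *distributions* only; two lists
  with identical criterion mixes but disjoint items score 1.
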