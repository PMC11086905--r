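# sfirank

Questionnaire short-form construction via cross-validated Shapley feature
rankings.

## The problem

Long self-report scales are impractical in fast-paced clinical settings.
`sfirank` implements a data-driven item-reduction pipeline for a 61-item
suicide-risk questionnaire (0–4 Likert responses covering the five Suicide
Crisis Syndrome criteria: **A** entrapment, **B1** affective disturbance,
**B2** loss of cognitive control, **B3** hyperarousal, **B4** social
withdrawal), ranking items by how much they contribute to predicting two
binary screener-derived outcomes — any suicidal ideation (**SI**, any "yes"
on screener items 1–5) and ideation with preparatory behavior (**SI-P**,
"yes" on item 6) — and assembling a short form under per-criterion quotas.

## The statistic

Let a cohort of *n* respondents with *p* items be split into *K* stratified
folds, repeated *R* times. Each of the *R·K* fold-models is an L2-penalised
logistic regression fit on the training folds; Shapley attributions
φ<sub>ij</sub> are computed on the held-out fold (closed-form linear SHAP on
the log-odds margin, φ<sub>ij</sub> = β<sub>j</sub>(z<sub>ij</sub> −
z̄<sub>j</sub>), with exact-enumeration and Kernel SHAP routes as cross-checks)
and aggregated to a global importance mean<sub>i</sub>|φ<sub>ij</sub>|. The
**SHAP Feature Importance** of item *j* is

> SFI(j) = #{ fold-models in which j ranks among the top-k by global importance },

an integer in [0, R·K] (at the defaults R = 1000, K = 4 the ceiling is 4000).
Whenever p > k, ΣSFI = k·R·K, an identity asserted on every run. Items are
ranked by SFI; the top-10 criterion distribution is compared with an 8-item
reference short form (similarity = 1 − ½·L1 between criterion proportion
vectors); and the final 9-item short form takes the top two items per
criterion (one for social withdrawal), falling back to the other outcome's
ranking when a criterion is missing.

Because the original survey data are not available, the package ships a
synthetic-cohort generator (5 correlated latent factors, graded-response
ordinal items, logistic outcomes calibrated to target prevalences of 19.11%
and 2.33%) whose default calibration reproduces the instrument's reported
total-score reliability (Cronbach's α ≈ .98).

## Worked example

```r
library(sfirank)

# 1. simulate a cohort with the documented default calibration
cohort <- generate_cohort(synthetic_config(n = 2000, seed = 42))
cronbach_alpha(cohort$responses)            # 0.983

# 2. rank items by SFI under repeated stratified 4-fold CV (demo scale R = 50)
res <- run_repeated_cv(cohort, outcome = "SI",
                       config = cv_config(n_reps = 50, seed = 1))
print(res$ranking)
#> <ranking_table> outcome SI (200 fold-models), 61 items; top 10:
#>  rank item_id sfi criterion
#>     1  SCI-23 194        B3
#>     2  SCI-13 183         A
#>     3  SCI-31 175        B3
#>     ...
round(res$metrics, 3)
#> accuracy 0.835  precision 0.630  recall 0.387
#> balanced_accuracy 0.665  auroc 0.807  auprc 0.552
```

An SFI of 194 means the item appeared in the top 20 of 194 of the 200
fold-models; the ceiling here is R·K = 200. On this synthetic cohort all
five factors carry signal, so the top ranks mix criteria; the held-out
metrics show the imbalance-typical pattern (high accuracy, modest recall).

```r
# 3. compare published rankings to the 8-item reference form
bank <- default_item_bank()
ref  <- default_reference_short_form(bank)
si   <- read_ranking_table(system.file("extdata", "published_ranking_si.csv",
                                       package = "sfirank"), "SI")
sip  <- read_ranking_table(system.file("extdata", "published_ranking_sip.csv",
                                       package = "sfirank"), "SI_P")
compare_rankings(si,  ref, bank)$similarity   # 0.55
compare_rankings(sip, ref, bank)$similarity   # 0.65  <- closer to the reference

# 4. assemble the nine-item short form (SI ranking primary, SI-P fallback)
assemble_short_form(si, sip, bank)
#> <short_form> 9 items (quotas: A=2 B1=2 B2=2 B3=2 B4=1)
#>  item_id criterion source source_rank
#>   SCI-12         A     SI           1
#>    SCI-4         A     SI           5
#>   SCI-38        B1     SI           4
#>   SCI-51        B1     SI           6
#>    SCI-3        B2     SI          10
#>   SCI-45        B2     SI          14
#>   SCI-60        B3     SI           2
#>   SCI-59        B3     SI           3
#>   SCI-74        B4     SI           9
```

The full pipeline (simulate → rank → compare → build, with a reproducible
run manifest) is `run_pipeline(config)` with a JSON config, or from the
shell via the bundled CLI:

```sh
Rscript inst/cli/sfirank run-all --config config.json
```

## Scope

The package reconstructs the *procedure* end to end and validates it on
synthetic cohorts; the original study cohort is unavailable, so published
per-item SFI values and real-data performance indices are used only as
fixture inputs (ranking tables), never as reproduction targets. See
`vignettes/shortform-construction.Rmd` for the model, calibration choices,
and what the synthetic validation does and does not establish.
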