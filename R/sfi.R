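# The core procedure: repeated stratified k-fold cross-validation, per-fold
# top-k extraction from global SHAP importances, and aggregation into the
# SFI (SHAP Feature Importance) frequency statistic and ranking table.
#
# SFI counts per *fold-model*: with R repetitions of K-fold CV the ceiling
# is R*K (4000 at the defaults R=1000, K=4), which is the only reading
# consistent with the statistic's published maxima.

#' Cross-validation configuration
#'
#' @param n_folds folds per repetition (default 4).
#' @param n_reps repetitions (default 1000).
#' @param top_k items stored per fold-model (default 20; capped at p).
#' @param seed master seed; repetition `r` uses `seed + r`.
#' @param l2_penalty ridge penalty passed to [fit_logistic()].
#' @param threshold probability cut-off for the thresholded metrics.
#' @param shap_rows rows attributions are computed on: `"test_fold"`
#'   (default; importance reflects generalization) or `"train_fold"`.
#' @return a `cv_config` object.
#' @export
cv_config <- function(n_folds = 4L, n_reps = 1000L, top_k = 20L, seed = 1L,
                      l2_penalty = 1.0, threshold = 0.5,
                      shap_rows = c("test_fold", "train_fold")) {
  shap_rows <- match.arg(shap_rows)
  stop_if(n_folds < 2, "n_folds must be at least 2")
  stop_if(n_reps < 1, "n_reps must be at least 1")
  stop_if(top_k < 1, "top_k must be at least 1")
  structure(list(n_folds = as.integer(n_folds), n_reps = as.integer(n_reps),
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 l2_penalty = l2_penalty, threshold = threshold,
                 shap_rows = shap_rows),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Each class is shuffled independently and dealt round-robin to folds, so
#' per-class fold sizes differ by at most one and every fold keeps
#' approximately the global case/control proportion.
#'
#' @param y binary 0/1 labels; each class must have at least `n_folds`
#'   members.
#' @param n_folds number of folds.
#' @param seed integer seed (deterministic assignment).
#' @return integer vector `fold_of` in `1..n_folds`, one entry per
#'   observation.
#' @export
stratified_kfold_indices <- function(y, n_folds, seed) {
  y <- as.numeric(y)
  stop_if(!is_binary(y), "`y` must be binary 0/1")
  n_folds <- as.integer(n_folds)
  cnt <- table(factor(y, levels = c(0, 1)))
  if (any(cnt < n_folds)) {
    small <- names(cnt)[which.min(cnt)]
    stop(sprintf(paste0("class '%s' has only %d member(s), fewer than n_folds = %d; ",
                        "stratified folds are impossible (extreme imbalance)"),
                 small, min(cnt), n_folds), call. = FALSE)
  }
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold_of
}

#' Fit one fold-model and extract its top-k items
#'
#' Fits the logistic model on the out-of-fold (training) rows, computes
#' linear-SHAP attributions on the rows selected by `config$shap_rows`
#' (default the held-out fold) against the training-fold feature means,
#' aggregates to mean-|phi| global importance, and returns the `top_k` item
#' ids by importance (capped at p), ties broken by bank column order.
#'
#' @param X feature matrix (bank column order).
#' @param y binary outcome vector.
#' @param assignment fold assignment from [stratified_kfold_indices()].
#' @param fold held-out fold index.
#' @param config a [cv_config()].
#' @return list: `top_items` (ordered ids), `importance`, `metrics`
#'   (held-out [compute_metrics()] report).
#' @export
run_fold_model <- function(X, y, assignment, fold, config) {
  stopifnot(inherits(config, "cv_config"))
  X <- as.matrix(X)
  test <- assignment == fold
  stop_if(!any(test) || all(test), "fold index selects no or all rows")
  y_train <- y[!test]
  if (length(unique(y_train)) < 2) {
    stop(sprintf("training rows for fold %d contain a single class", fold),
         call. = FALSE)
  }
  model <- fit_logistic(X[!test, , drop = FALSE], y_train,
                        l2_penalty = config$l2_penalty)
  eval_rows <- if (config$shap_rows == "test_fold") test else !test
  shap <- linear_shapley(model, X[eval_rows, , drop = FALSE])
  imp <- global_importance(shap)
  ord <- order(-imp, seq_along(imp))          # stable: ties keep bank order
  k <- min(config$top_k, length(imp))
  metrics <- compute_metrics(y[test], predict_proba(model, X[test, , drop = FALSE]),
                             threshold = config$threshold,
                             strict_rank_metrics = FALSE)
  list(top_items = names(imp)[ord[seq_len(k)]], importance = imp,
       metrics = metrics)
}

#' Aggregate per-fold top-k sets into an SFI table
#'
#' `SFI(item)` is the number of fold-model top-k sets that contain the item;
#' the ceiling is the number of fold-models.
#'
#' @param fold_results list of character vectors (top-k item ids per
#'   fold-model).
#' @param bank an [item_bank()]; results may only contain bank ids.
#' @param outcome_label `"SI"` or `"SI_P"` (bookkeeping).
#' @return an `sfi_table`: named integer `counts` over all bank items,
#'   `n_fold_models`, `outcome_label`.
#' @export
accumulate_sfi <- function(fold_results, bank, outcome_label = "SI") {
  stopifnot(inherits(bank, "item_bank"))
  stop_if(length(fold_results) == 0, "no fold results to aggregate")
  # SFI counts fold-models *containing* an item, so duplicates within one
  # fold result must not double-count
  all_ids <- unlist(lapply(fold_results, unique), use.names = FALSE)
  unknown <- setdiff(unique(all_ids), bank$item_id)
  stop_if(length(unknown) > 0,
          paste0("fold results contain item(s) absent from bank: ",
                 paste(unknown, collapse = ", ")))
  counts <- table(factor(all_ids, levels = bank$item_id))
  structure(list(counts = stats::setNames(as.integer(counts), bank$item_id),
                 n_fold_models = length(fold_results),
                 outcome_label = outcome_label),
            class = "sfi_table")
}

#' @export
print.sfi_table <- function(x, ...) {
  top <- sort(x$counts, decreasing = TRUE)[1:min(5, length(x$counts))]
  cat(sprintf("<sfi_table> outcome %s, %d fold-models; top items: %s\n",
              x$outcome_label, x$n_fold_models,
              paste(sprintf("%s=%d", names(top), top), collapse = " ")))
  invisible(x)
}

#' Rank items by SFI
#'
#' Sorts by SFI descending; ties are broken by bank order (stable). Criterion
#' labels are attached from the bank.
#'
#' @param sfi an [accumulate_sfi()] result.
#' @param bank the [item_bank()].
#' @return a `ranking_table` data.frame with columns
#'   `rank, item_id, sfi, criterion` and attributes `outcome_label`,
#'   `n_fold_models`, `tie_rule`.
#' @export
rank_items <- function(sfi, bank) {
  stopifnot(inherits(sfi, "sfi_table"), inherits(bank, "item_bank"))
  counts <- sfi$counts[bank$item_id]
  ord <- order(-counts, seq_along(counts))
  out <- data.frame(rank = seq_along(ord),
                    item_id = bank$item_id[ord],
                    sfi = as.integer(counts[ord]),
                    criterion = bank$criterion[ord],
                    stringsAsFactors = FALSE)
  structure(out, outcome_label = sfi$outcome_label,
            n_fold_models = sfi$n_fold_models,
            tie_rule = "stable bank order",
            class = c("ranking_table", "data.frame"))
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("<ranking_table> outcome %s (%d fold-models), %d items; top 10:\n",
              attr(x, "outcome_label") %||% "?",
              attr(x, "n_fold_models") %||% NA_integer_, nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' Construct a ranking table directly (e.g. from published values)
#' @param rank,item_id,sfi,criterion column vectors.
#' @param outcome_label bookkeeping label.
#' @param n_fold_models SFI ceiling, if known.
#' @return a `ranking_table`.
#' @export
ranking_table <- function(rank, item_id, sfi, criterion,
                          outcome_label = "SI", n_fold_models = NA_integer_) {
  out <- data.frame(rank = as.integer(rank), item_id = as.character(item_id),
                    sfi = as.integer(sfi), criterion = as.character(criterion),
                    stringsAsFactors = FALSE)
  stop_if(is.unsorted(-out$sfi), "SFI must be non-increasing in rank")
  structure(out, outcome_label = outcome_label,
            n_fold_models = n_fold_models, tie_rule = "as supplied",
            class = c("ranking_table", "data.frame"))
}

#' Read / write ranking tables as CSV (`rank,item_id,sfi,criterion`)
#' @param ranking a `ranking_table`.
#' @param path file path.
#' @return `path` (write) / a `ranking_table` (read).
#' @export
write_ranking_table <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranking_table"))
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_ranking_table
#' @param outcome_label label attached on read.
#' @export
read_ranking_table <- function(path, outcome_label = "SI") {
  stop_if(!file.exists(path), paste0("ranking file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  ranking_table(raw$rank, raw$item_id, raw$sfi, raw$criterion,
                outcome_label = outcome_label)
}

#' Repeated stratified cross-validation with SFI aggregation
#'
#' The pipeline's core loop. For each repetition `r` (seeded `seed + r`) the
#' cohort is split into stratified folds; each fold-model is fit on the
#' training rows, attributed with linear SHAP, and its top-k item set stored.
#' Counts are aggregated into an SFI table and ranking; held-out metrics are
#' averaged across fold-models. Fold-models whose training rows degenerate
#' to a single class are dropped (with a warning and a logged count) rather
#' than aborting the run; the SFI ceiling `n_fold_models` shrinks
#' accordingly.
#'
#' When `p > top_k` the conservation identity
#' `sum(SFI) == top_k * n_fold_models` is asserted on every run.
#'
#' @param cohort a [generate_cohort()] result, or any list with `responses`
#'   (matrix), `outcomes` ([outcome_labels()]) and `bank` ([item_bank()]).
#' @param outcome `"SI"` or `"SI_P"`.
#' @param config a [cv_config()].
#' @return list: `sfi` (sfi_table), `ranking` (ranking_table), `metrics`
#'   (named means across fold-models), `n_failed` (dropped fold-models).
#' @export
run_repeated_cv <- function(cohort, outcome = c("SI", "SI_P"), config = cv_config()) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(config, "cv_config"))
  X <- as.matrix(cohort$responses)
  bank <- cohort$bank
  y <- if (outcome == "SI") cohort$outcomes$si else cohort$outcomes$si_p
  stop_if(length(y) != nrow(X), "outcome length does not match responses")

  results <- vector("list", config$n_reps * config$n_folds)
  metric_names <- c("accuracy", "precision", "recall", "balanced_accuracy",
                    "auroc", "auprc")
  msum <- stats::setNames(numeric(length(metric_names)), metric_names)
  n_ok <- 0L
  n_failed <- 0L
  for (r in seq_len(config$n_reps)) {
    assignment <- stratified_kfold_indices(y, config$n_folds,
                                           seed = config$seed + r)
    for (fold in seq_len(config$n_folds)) {
      res <- tryCatch(run_fold_model(X, y, assignment, fold, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        next
      }
      n_ok <- n_ok + 1L
      results[[n_ok]] <- res$top_items
      msum <- msum + unlist(res$metrics[metric_names])
    }
  }
  if (n_failed > 0) {
    warning(sprintf("%d of %d fold-models failed (single-class training rows) and were excluded",
                    n_failed, n_failed + n_ok), call. = FALSE)
  }
  stop_if(n_ok == 0, "every fold-model failed; nothing to aggregate")
  sfi <- accumulate_sfi(results[seq_len(n_ok)], bank, outcome_label = outcome)
  if (ncol(X) > config$top_k) {
    stopifnot(sum(sfi$counts) == config$top_k * sfi$n_fold_models)
  }
  list(sfi = sfi,
       ranking = rank_items(sfi, bank),
       metrics = msum / n_ok,
       n_failed = n_failed)
}
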