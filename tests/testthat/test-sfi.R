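test_that("stratified folds deal classes round-robin", {
  y <- c(rep(1, 8), rep(0, 92))
  f <- stratified_kfold_indices(y, 4, seed = 1)
  for (k in 1:4) {
    expect_equal(sum(f == k & y == 1), 2L)
    expect_equal(sum(f == k & y == 0), 23L)
  }
  # deterministic under a fixed seed, different under another
  expect_identical(f, stratified_kfold_indices(y, 4, seed = 1))
  expect_false(identical(f, stratified_kfold_indices(y, 4, seed = 2)))
  # minority class smaller than the fold count: the SI-P hazard
  expect_error(stratified_kfold_indices(c(1, 1, 1, rep(0, 97)), 4, seed = 1),
               "fewer than n_folds")
})

test_that("per-class fold sizes never differ by more than one", {
  set.seed(40)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.5))
    k <- sample(2:5, 1)
    if (min(table(y)) < k) next
    f <- stratified_kfold_indices(y, k, seed = rep)
    for (cls in 0:1) {
      sizes <- table(f[y == cls])
      expect_lte(max(sizes) - min(sizes), 1)
    }
  }
})

test_that("run_fold_model caps top_k at p and reports held-out metrics", {
  set.seed(41)
  n <- 200; p <- 10
  bank <- tiny_bank(p)
  X <- matrix(sample(0:4, n * p, TRUE), n, p,
              dimnames = list(NULL, bank$item_id))
  y <- rbinom(n, 1, plogis(scale(X[, 1]) * 1.5))
  f <- stratified_kfold_indices(y, 4, seed = 1)
  res <- run_fold_model(X, y, f, 1, cv_config(top_k = 20, n_reps = 1))
  expect_length(res$top_items, p)          # capped
  expect_setequal(res$top_items, bank$item_id)
  expect_s3_class(res$metrics, "metrics_report")
  # the lone informative item ranks first
  expect_equal(res$top_items[1], "T-1")
})

test_that("single-class training rows are a reported error", {
  n <- 40
  X <- matrix(sample(0:4, n * 3, TRUE), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- c(rep(1, 10), rep(0, 30))
  assignment <- c(rep(1L, 10), rep(2L, 10), rep(3L, 10), rep(4L, 10))
  # fold 1 holds every positive: training on folds 2-4 sees one class
  expect_error(run_fold_model(X, y, assignment, 1,
                              cv_config(n_reps = 1)), "single class")
})

test_that("SFI accumulation counts appearances per fold-model", {
  bank <- tiny_bank(5)
  res <- list(c("T-1", "T-2"), c("T-1", "T-3"), c("T-1", "T-2"), c("T-4", "T-1"))
  sfi <- accumulate_sfi(res, bank, "SI")
  expect_equal(unname(sfi$counts[c("T-1", "T-2", "T-3", "T-4", "T-5")]),
               c(4L, 2L, 1L, 1L, 0L))
  expect_equal(sfi$n_fold_models, 4L)
  # conservation with p > top_k
  expect_equal(sum(sfi$counts), 2 * 4)
  expect_error(accumulate_sfi(list(c("T-1", "NOPE")), bank), "absent from bank")
  expect_error(accumulate_sfi(list(), bank), "no fold results")
})

test_that("an ever-present item saturates at the fold-model ceiling", {
  bank <- default_item_bank()
  top20 <- bank$item_id[1:20]           # includes SCI-12 by construction? keep explicit
  top20[1] <- "SCI-12"
  results <- rep(list(unique(top20)), 4000)
  sfi <- accumulate_sfi(results, bank, "SI")
  expect_equal(unname(sfi$counts["SCI-12"]), 4000L)
  expect_equal(max(sfi$counts), 4000L)
  expect_equal(sfi$n_fold_models, 1000L * 4L)
})

test_that("ranking sorts by SFI with stable bank-order ties", {
  bank <- tiny_bank(4)
  mk_sfi <- function(counts) structure(
    list(counts = counts, n_fold_models = 4000L, outcome_label = "SI"),
    class = "sfi_table")
  r <- rank_items(mk_sfi(c(`T-1` = 3972L, `T-2` = 4000L, `T-3` = 100L,
                           `T-4` = 4000L)), bank)
  expect_equal(r$item_id, c("T-2", "T-4", "T-1", "T-3"))
  expect_equal(r$rank, 1:4)
  expect_equal(r$sfi[1:2], c(4000L, 4000L))   # tie kept, earlier bank item first
  # all equal: ranking is bank order
  r2 <- rank_items(mk_sfi(setNames(rep(7L, 4), bank$item_id)), bank)
  expect_equal(r2$item_id, bank$item_id)
})

test_that("repeated CV conserves SFI mass and is seed-deterministic", {
  bank <- tiny_bank(3)
  set.seed(50)
  n <- 60
  X <- matrix(sample(0:4, n * 3, TRUE), n, 3,
              dimnames = list(NULL, bank$item_id))
  y <- rep(c(0, 1), 30)
  cohort <- list(bank = bank, responses = X,
                 outcomes = outcome_labels(y, y))
  res <- run_repeated_cv(cohort, "SI", cv_config(n_folds = 2, n_reps = 1,
                                                 top_k = 2, seed = 7))
  expect_equal(sum(res$sfi$counts), 4L)       # R=1, K=2, top_k=2
  expect_equal(res$sfi$n_fold_models, 2L)

  res2 <- run_repeated_cv(cohort, "SI", cv_config(n_folds = 2, n_reps = 1,
                                                  top_k = 2, seed = 7))
  expect_identical(res$sfi$counts, res2$sfi$counts)
  expect_identical(res$ranking$item_id, res2$ranking$item_id)
})

test_that("under permuted labels items are exchangeable across datasets", {
  # within a single dataset spurious sample correlations persist across
  # repetitions, so exchangeability must be judged across independent null
  # datasets: no item may be systematically favoured
  p <- 12; n <- 240; k <- 4; D <- 12
  bank <- tiny_bank(p)
  set.seed(51)
  freq <- matrix(0, D, p, dimnames = list(NULL, bank$item_id))
  top_item <- character(D)
  for (d in seq_len(D)) {
    X <- matrix(sample(0:4, n * p, TRUE), n, p,
                dimnames = list(NULL, bank$item_id))
    y <- sample(rep(c(0, 1), c(180, 60)))     # labels independent of X
    cohort <- list(bank = bank, responses = X, outcomes = outcome_labels(y, y))
    res <- run_repeated_cv(cohort, "SI",
                           cv_config(n_reps = 4, top_k = k, seed = 300 + d))
    freq[d, ] <- res$sfi$counts / res$sfi$n_fold_models
    top_item[d] <- res$ranking$item_id[1]
  }
  avg <- colMeans(freq)
  expect_equal(mean(avg), k / p, tolerance = 1e-10)   # conservation restated
  # per-item mean inclusion within 3 sigma of k/p (freq variance <= 1/4)
  expect_lt(max(abs(avg - k / p)), 3 * sqrt(0.25 / D))
  # no single item tops a majority of independent null datasets
  expect_lt(max(table(top_item)), D / 2)
})

test_that("raising an item's outcome-factor loading raises its SFI", {
  base_cfg <- recovery_config(n = 600, seed = 61)
  weak_load <- base_cfg$loadings
  target <- which(base_cfg$bank$criterion == "A")[1]
  weak_load[target, ] <- 0                    # disconnect the item entirely
  weak <- generate_cohort(synthetic_config(
    n = 600, loadings = weak_load, factor_corr = base_cfg$factor_corr,
    outcome_coeffs_si = base_cfg$outcome_coeffs_si,
    target_prev_si = 0.19, seed = 61))
  strong <- generate_cohort(base_cfg)
  cvc <- cv_config(n_reps = 10, seed = 5)
  id <- base_cfg$bank$item_id[target]
  sfi_weak <- run_repeated_cv(weak, "SI", cvc)$sfi$counts[id]
  sfi_strong <- run_repeated_cv(strong, "SI", cvc)$sfi$counts[id]
  expect_gt(sfi_strong, sfi_weak)
})

test_that("ranking tables round-trip through CSV", {
  r <- published_si_ranking()
  expect_s3_class(r, "ranking_table")
  expect_equal(r$rank, 1:15)
  path <- tempfile(fileext = ".csv")
  write_ranking_table(r, path)
  back <- read_ranking_table(path)
  expect_equal(as.data.frame(back), as.data.frame(r))
  # non-monotone SFI is rejected
  expect_error(ranking_table(1:2, c("a", "b"), c(10L, 20L), c("A", "A")),
               "non-increasing")
})
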