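# random monotone step-function game over feature values, used to exercise
# the engines on something decidedly non-linear
random_step_predict <- function(p, seed) {
  set.seed(seed)
  cuts <- runif(p, -0.5, 0.5)
  wts <- rnorm(p)
  inter <- rnorm(1)
  function(X) {
    X <- as.matrix(X)
    as.numeric((X > matrix(cuts, nrow(X), p, byrow = TRUE)) %*% wts) + inter
  }
}

test_that("exact enumeration satisfies the Shapley axioms", {
  # dummy: a player the game ignores gets zero
  v <- function(S) sum(S %in% c(1, 3))
  phi <- exact_shapley(v, 4)
  expect_equal(phi[2], 0)
  expect_equal(phi[4], 0)
  # symmetry: interchangeable players split equally
  v2 <- function(S) as.numeric(1 %in% S) + as.numeric(2 %in% S)
  phi2 <- exact_shapley(v2, 2)
  expect_equal(phi2[1], phi2[2])
  # efficiency by construction
  expect_equal(sum(phi), v(1:4) - v(integer(0)))
  expect_error(exact_shapley(v, 15), "kernel_shapley")
})

test_that("worked linear example: f = 2 x1 + 3 x2 at x = (1,1), background 0", {
  f <- function(X) 2 * X[, 1] + 3 * X[, 2]
  v <- coalition_value_fn(f, c(1, 1), matrix(0, 1, 2))
  expect_equal(exact_shapley(v, 2), c(2, 3))
})

test_that("axioms hold on random games against the enumeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(4:8, 1)
    vals <- rnorm(2^p)               # arbitrary random game, v(empty) free
    v <- function(S) vals[sum(bitwShiftL(1L, S - 1L)) + 1L]
    phi <- exact_shapley(v, p)
    # efficiency
    expect_equal(sum(phi), v(seq_len(p)) - v(integer(0)), tolerance = 1e-10)
    # linearity: shapley(v + w) = shapley(v) + shapley(w)
    vals2 <- rnorm(2^p)
    w <- function(S) vals2[sum(bitwShiftL(1L, S - 1L)) + 1L]
    vw <- function(S) v(S) + w(S)
    expect_equal(exact_shapley(vw, p), phi + exact_shapley(w, p),
                 tolerance = 1e-10)
  }
})

test_that("linear SHAP is the closed form of the enumeration oracle", {
  set.seed(20)
  p <- 8; n <- 400
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- rbinom(n, 1, plogis(X %*% rnorm(p)))
  model <- fit_logistic(X, y)
  bg <- matrix(model$feature_means, 1, dimnames = list(NULL, colnames(X)))
  shap <- linear_shapley(model, X[1:5, , drop = FALSE])
  for (i in 1:5) {
    v <- coalition_value_fn(function(M) predict_margin(model, M),
                            X[i, ], bg)
    expect_equal(unname(shap$values[i, ]), exact_shapley(v, p),
                 tolerance = 1e-10)
  }
  # efficiency row by row
  margins <- predict_margin(model, X[1:5, , drop = FALSE])
  expect_equal(unname(shap$base_value + rowSums(shap$values)), margins,
               tolerance = 1e-8)
  # base value at training means is the intercept
  expect_equal(shap$base_value, model$intercept)
  # x at the background means: all-zero attributions
  z <- linear_shapley(model, bg)
  expect_equal(max(abs(z$values)), 0)
})

test_that("attributions are invariant to feature rescaling", {
  model <- structure(list(
    intercept = 0.2, coefficients = c(a = 1.5, b = -0.7),
    feature_means = c(a = 1, b = 2), feature_scales = c(a = 2, b = 0.5),
    item_ids = c("a", "b"), l2_penalty = 0, converged = TRUE, n_iter = 1L),
    class = "fitted_logistic")
  # same model expressed on a stretched feature scale
  stretched <- model
  stretched$feature_means["a"] <- 10
  stretched$feature_scales["a"] <- 20
  X <- matrix(c(3, 4), 1, dimnames = list(NULL, c("a", "b")))
  X2 <- X; X2[, "a"] <- 10 + (3 - 1) / 2 * 20   # same standardized position
  s1 <- linear_shapley(model, X)
  s2 <- linear_shapley(stretched, X2)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
})

test_that("kernel SHAP matches the oracle on non-linear games", {
  p <- 8
  set.seed(30)
  bg <- matrix(rnorm(5 * p), 5, p)
  for (seed in 1:3) {
    f <- random_step_predict(p, seed)
    x <- rnorm(p)
    ks <- kernel_shapley(f, x, bg)
    v <- coalition_value_fn(f, x, bg)
    expect_equal(unname(ks$phi), exact_shapley(v, p), tolerance = 1e-6)
    # efficiency as a constraint
    expect_equal(ks$base_value + sum(ks$phi), mean(f(matrix(x, 1))) ,
                 tolerance = 1e-8)
  }
})

test_that("kernel SHAP equals linear SHAP for linear models", {
  set.seed(31)
  p <- 12; n <- 300
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- rbinom(n, 1, plogis(X %*% rnorm(p, sd = 0.5)))
  model <- fit_logistic(X, y)
  bg <- matrix(model$feature_means, 1, dimnames = list(NULL, colnames(X)))
  ks <- kernel_shapley(function(M) predict_margin(model, M), X[7, ], bg)
  ls <- linear_shapley(model, X[7, , drop = FALSE])
  expect_equal(unname(ks$phi), unname(ls$values[1, ]), tolerance = 1e-8)

  # sampling branch (p > 14): the linear game is still solved exactly
  p2 <- 20
  X2 <- matrix(rnorm(100 * p2), 100, p2,
               dimnames = list(NULL, paste0("x", 1:p2)))
  y2 <- rbinom(100, 1, plogis(X2 %*% rnorm(p2, sd = 0.4)))
  m2 <- fit_logistic(X2, y2)
  bg2 <- matrix(m2$feature_means, 1, dimnames = list(NULL, colnames(X2)))
  ks2 <- kernel_shapley(function(M) predict_margin(m2, M), X2[3, ], bg2,
                        config = list(n_coalitions = 3000, seed = 2))
  ls2 <- linear_shapley(m2, X2[3, , drop = FALSE])
  expect_equal(unname(ks2$phi), unname(ls2$values[1, ]), tolerance = 1e-6)
})

test_that("constant models attribute nothing", {
  ks <- kernel_shapley(function(M) rep(1.3, nrow(M)), rnorm(5),
                       matrix(rnorm(15), 3, 5))
  expect_equal(max(abs(ks$phi)), 0, tolerance = 1e-10)
  expect_equal(ks$base_value, 1.3)
})

test_that("global importance aggregates |phi| and respects invariances", {
  vals <- matrix(c(1, -2, 3, -1, 2, -3), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  sm <- shap_matrix(vals, base_value = 0)
  expect_equal(unname(global_importance(sm)), c(1, 2, 3))
  # single row: its absolute values
  one <- shap_matrix(vals[1, , drop = FALSE], 0)
  expect_equal(unname(global_importance(one)), c(1, 2, 3))
  # duplicating rows changes nothing
  dup <- shap_matrix(vals[c(1, 2, 1, 2), ], 0)
  expect_equal(global_importance(dup), global_importance(sm))
  # signed means cancel here
  expect_equal(unname(global_importance(sm, "mean_signed")), c(0, 0, 0))
  # a zero-coefficient feature gets zero importance through the linear route
  model <- structure(list(
    intercept = 0, coefficients = c(a = 1, b = 0),
    feature_means = c(a = 0, b = 0), feature_scales = c(a = 1, b = 1),
    item_ids = c("a", "b"), l2_penalty = 0, converged = TRUE, n_iter = 1L),
    class = "fitted_logistic")
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(global_importance(linear_shapley(model, X))["b"]), 0)
})

test_that("SHAP matrices serialize with their base value", {
  sm <- shap_matrix(matrix(1:4 / 7, 2, 2, dimnames = list(NULL, c("a", "b"))),
                    base_value = -0.25)
  path <- tempfile(fileext = ".csv")
  write_shap_matrix(sm, path)
  lines <- readLines(path)
  expect_match(lines[1], "base_value: -0.25")
  back <- read.csv(path, comment.char = "#")
  expect_equal(as.matrix(back), sm$values, ignore_attr = TRUE)
})
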