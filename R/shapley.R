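# Shapley-value attribution on the model's margin (log-odds) scale:
# exact enumeration oracle, closed-form linear SHAP, and a Kernel SHAP
# weighted-least-squares approximation. Attributions use the interventional
# (independent-features) value function: out-of-coalition features are
# replaced by background values.

#' Exact Shapley values by coalition enumeration
#'
#' Computes `phi_i = sum over S not containing i of
#' |S|! (p-|S|-1)! / p! * (v(S + i) - v(S))` by full `2^p` enumeration.
#' Intended as the oracle against which the closed-form and kernel routes are
#' checked; limited to `p <= 14`.
#'
#' @param value_fn set function: takes an integer vector of feature indices
#'   (possibly empty) and returns a scalar coalition value.
#' @param p number of players (features).
#' @return numeric attribution vector of length `p`.
#' @export
exact_shapley <- function(value_fn, p) {
  stop_if(p < 1, "p must be at least 1")
  stop_if(p > 14,
          "exact enumeration is limited to p <= 14; use kernel_shapley() for larger p")
  n_sets <- bitwShiftL(1L, p)
  v <- numeric(n_sets)
  sizes <- integer(n_sets)
  for (m in 0:(n_sets - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    v[m + 1L] <- value_fn(S)
    sizes[m + 1L] <- length(S)
  }
  # weight by |S| for S excluding i
  w <- exp(lfactorial(0:(p - 1L)) + lfactorial(p - 1L - (0:(p - 1L))) -
             lfactorial(p))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    masks <- 0:(n_sets - 1L)
    excl <- masks[bitwAnd(masks, bit) == 0L]
    phi[i] <- sum(w[sizes[excl + 1L] + 1L] *
                    (v[bitwOr(excl, bit) + 1L] - v[excl + 1L]))
  }
  phi
}

#' Interventional coalition value function for a prediction
#'
#' Builds the set function used by the exact and kernel routes: the value of
#' coalition `S` is the mean model output over the background sample with the
#' features in `S` fixed at `x`'s values and the rest left at background
#' values.
#'
#' @param predict_fn function taking a feature matrix, returning a numeric
#'   vector (typically the margin).
#' @param x single evaluation row (numeric vector).
#' @param background matrix of background rows (same width as `x`).
#' @return a function `v(S)` over integer index vectors.
#' @export
coalition_value_fn <- function(predict_fn, x, background) {
  background <- as.matrix(background)
  stop_if(nrow(background) < 1, "background sample is empty")
  stop_if(ncol(background) != length(x),
          "background width does not match the evaluation row")
  function(S) {
    B <- background
    if (length(S) > 0) B[, S] <- matrix(x[S], nrow(B), length(S), byrow = TRUE)
    mean(predict_fn(B))
  }
}

#' Closed-form Shapley values for a linear model
#'
#' For a model linear in its (standardized) features, the Shapley value of
#' feature `j` at row `i` under the interventional value function is
#' `beta_j * (z_ij - z_bg_j)` on the margin scale; the base value is the
#' margin at the background means. Efficiency
#' (`base + sum(phi) == margin`) holds exactly.
#'
#' @param model a [fit_logistic()] result.
#' @param X_eval rows to attribute (feature matrix, model's column order).
#' @param background_means background feature means on the raw scale
#'   (default: the model's training means, giving base value = intercept).
#' @return a `shap_matrix` object: `values` (n x p, log-odds units),
#'   `base_value`, `item_ids`, `background_summary`.
#' @export
linear_shapley <- function(model, X_eval, background_means = NULL) {
  stopifnot(inherits(model, "fitted_logistic"))
  X_eval <- check_feature_alignment(model, X_eval)
  bg <- background_means %||% model$feature_means
  stop_if(length(bg) != length(model$item_ids),
          "background_means length does not match the model")
  Zx <- sweep(sweep(X_eval, 2L, model$feature_means), 2L,
              model$feature_scales, "/")
  zbg <- (bg - model$feature_means) / model$feature_scales
  phi <- sweep(sweep(Zx, 2L, zbg), 2L, model$coefficients, "*")
  dimnames(phi) <- list(rownames(X_eval), model$item_ids)
  base <- model$intercept + sum(model$coefficients * zbg)
  shap_matrix(phi, base_value = base, item_ids = model$item_ids,
              background_summary = bg)
}

#' Construct a SHAP attribution matrix
#' @param values n x p attribution matrix (log-odds units).
#' @param base_value expected margin over the background.
#' @param item_ids column ids.
#' @param background_summary background feature means used.
#' @return a `shap_matrix` object.
#' @export
shap_matrix <- function(values, base_value, item_ids = colnames(values),
                        background_summary = NULL) {
  values <- as.matrix(values)
  stop_if(is.null(item_ids) || length(item_ids) != ncol(values),
          "item_ids must label every attribution column")
  colnames(values) <- item_ids
  structure(list(values = values, base_value = base_value,
                 item_ids = item_ids,
                 background_summary = background_summary),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d rows x %d items, base value %.4f (log-odds)\n",
              nrow(x$values), ncol(x$values), x$base_value))
  invisible(x)
}

#' Write a SHAP matrix to CSV
#'
#' Rows are respondents, columns items; the base value is recorded in a
#' `# base_value:` header comment line.
#'
#' @param shap a [shap_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shap_matrix <- function(shap, path) {
  stopifnot(inherits(shap, "shap_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# base_value: %.17g", shap$base_value), con)
  utils::write.csv(as.data.frame(shap$values), con, row.names = FALSE)
  invisible(path)
}

#' Kernel SHAP: weighted-least-squares Shapley approximation
#'
#' Regresses coalition values on coalition indicator vectors under the
#' Shapley kernel weights `(p-1) / (choose(p,k) * k * (p-k))`, with the
#' efficiency constraint `sum(phi) = f(x) - E[f]` enforced by elimination.
#' All `2^p - 2` proper coalitions are enumerated when `2^p <= 2^14`;
#' otherwise coalitions are sampled by kernel weight under a fixed seed.
#'
#' @param predict_fn function over feature matrices returning the margin.
#' @param x_eval single evaluation row.
#' @param background_sample background matrix (nonempty).
#' @param config list: `n_coalitions` (sampling budget when `p > 14`,
#'   default 4096) and `seed` (default 1).
#' @return list: `phi` (attribution vector), `base_value`.
#' @export
kernel_shapley <- function(predict_fn, x_eval, background_sample,
                           config = list()) {
  x <- as.numeric(x_eval)
  p <- length(x)
  stop_if(p < 2, "kernel SHAP needs at least two features")
  v <- coalition_value_fn(predict_fn, x, background_sample)
  v0 <- v(integer(0))
  vfull <- v(seq_len(p))
  delta <- vfull - v0

  if (p <= 14) {
    n_sets <- bitwShiftL(1L, p) - 2L
    Z <- matrix(0, n_sets, p)
    k <- integer(n_sets)
    vals <- numeric(n_sets)
    for (m in seq_len(n_sets)) {
      S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      Z[m, S] <- 1
      k[m] <- length(S)
      vals[m] <- v(S)
    }
    w <- (p - 1) / (choose(p, k) * k * (p - k))
  } else {
    n_coal <- as.integer(config$n_coalitions %||% 4096L)
    seed <- as.integer(config$seed %||% 1L)
    size_w <- (p - 1) / ((1:(p - 1)) * (p - (1:(p - 1))))  # kernel mass per size
    sizes <- with_seed(seed, sample(1:(p - 1), n_coal, replace = TRUE,
                                    prob = size_w / sum(size_w)))
    Z <- matrix(0, n_coal, p)
    with_seed(seed + 1L, for (m in seq_len(n_coal)) {
      Z[m, sample.int(p, sizes[m])] <- 1
    })
    vals <- apply(Z, 1L, function(z) v(which(z == 1)))
    w <- rep(1, n_coal)  # importance sampling: weights absorbed by sampling
  }

  # efficiency by elimination: phi_p = delta - sum(phi_{-p})
  yv <- vals - v0 - Z[, p] * delta
  A <- Z[, -p, drop = FALSE] - Z[, p]
  AW <- A * w
  M <- crossprod(AW, A)
  rhs <- as.numeric(crossprod(AW, yv))
  phi_head <- tryCatch(solve(M, rhs), error = function(e) {
    stop("kernel SHAP system is singular (degenerate background or coalition sample): ",
         conditionMessage(e), call. = FALSE)
  })
  phi <- c(phi_head, delta - sum(phi_head))
  names(phi) <- names(x_eval) %||% colnames(background_sample)
  list(phi = phi, base_value = v0)
}

#' Global importance from a SHAP matrix
#'
#' Per-item aggregation of attributions across evaluation rows. The default
#' is the mean absolute attribution (the usual summary convention -- signed
#' means cancel and cannot rank items); the signed mean is available.
#'
#' @param shap a [shap_matrix()].
#' @param type `"mean_abs"` (default) or `"mean_signed"`.
#' @return named numeric vector (an importance vector), length p.
#' @export
global_importance <- function(shap, type = c("mean_abs", "mean_signed")) {
  stopifnot(inherits(shap, "shap_matrix"))
  stop_if(nrow(shap$values) < 1, "SHAP matrix has no rows")
  type <- match.arg(type)
  out <- if (type == "mean_abs") colMeans(abs(shap$values))
         else colMeans(shap$values)
  stats::setNames(as.numeric(out), shap$item_ids)
}
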