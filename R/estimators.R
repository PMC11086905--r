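# L2-penalised logistic regression by IRLS on standardized features.
#
# This is the implemented estimator (the strongest performer for this
# problem class); tree ensembles can be plugged in behind the same
# fit/predict contract but are not re-implemented here.

#' Fit an L2-penalised logistic regression (IRLS)
#'
#' Features are standardized internally (mean 0, SD 1); the ridge penalty
#' `0.5 * l2_penalty * sum(beta^2)` applies to the standardized coefficients
#' and never to the intercept. Newton/IRLS iterations stop when the maximum
#' absolute penalized score falls below `tol` (default 1e-8) or after
#' `max_iter` iterations.
#'
#' @param X numeric feature matrix (columns named with item ids) -- a
#'   [response_matrix()] works directly. Zero columns are allowed
#'   (intercept-only fit).
#' @param y binary 0/1 outcome vector; both classes must be present.
#' @param l2_penalty nonnegative ridge penalty on the standardized scale
#'   (default 1.0, the conventional weak default).
#' @param max_iter,tol convergence controls.
#' @return a `fitted_logistic` object: `intercept`, `coefficients`
#'   (standardized scale), `feature_means`, `feature_scales`, `item_ids`,
#'   `converged`, `n_iter`.
#' @export
fit_logistic <- function(X, y, l2_penalty = 1.0, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stop_if(!is_binary(y), "`y` must be binary 0/1")
  stop_if(nrow(X) != length(y), "X and y sizes disagree")
  stop_if(length(y) < 2, "need at least two observations")
  stop_if(length(unique(y)) < 2,
          "y contains a single class; a classifier cannot be fit")
  stop_if(anyNA(X), "X contains missing values")
  stop_if(l2_penalty < 0, "l2_penalty must be nonnegative")

  p <- ncol(X)
  item_ids <- colnames(X) %||% if (p > 0) paste0("x", seq_len(p)) else character(0)
  mu <- if (p > 0) colMeans(X) else numeric(0)
  sdv <- if (p > 0) apply(X, 2L, stats::sd) else numeric(0)
  sdv[sdv == 0 | is.na(sdv)] <- 1  # constant column: coefficient shrinks to 0
  Z <- if (p > 0) sweep(sweep(X, 2L, mu), 2L, sdv, "/") else X

  beta <- numeric(p)
  b0 <- stats::qlogis(mean(y))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- b0 + if (p > 0) as.numeric(Z %*% beta) else 0
    prob <- stats::plogis(eta)
    # penalized score
    r <- y - prob
    g0 <- sum(r)
    g <- if (p > 0) as.numeric(crossprod(Z, r)) - l2_penalty * beta else numeric(0)
    if (max(abs(c(g0, g))) < tol) { converged <- TRUE; break }
    w <- pmax(prob * (1 - prob), 1e-12)
    if (p > 0) {
      Zw <- Z * w
      H <- rbind(c(sum(w), colSums(Zw)),
                 cbind(colSums(Zw), crossprod(Z, Zw) + diag(l2_penalty, p)))
      step <- tryCatch(solve(H, c(g0, g)),
                       error = function(e) stop("IRLS normal equations are singular: ",
                                                conditionMessage(e), call. = FALSE))
      b0 <- b0 + step[1L]
      beta <- beta + step[-1L]
    } else {
      b0 <- b0 + g0 / sum(w)
    }
    if (!all(is.finite(c(b0, beta))) || max(abs(beta)) > 1e6) {
      stop("logistic fit diverged (likely perfect separation); ",
           "use a positive l2_penalty", call. = FALSE)
    }
  }
  if (!converged) {
    stop(sprintf(paste0("IRLS did not converge in %d iterations ",
                        "(max |score| still above %g); perfect separation? ",
                        "consider a positive l2_penalty"), max_iter, tol),
         call. = FALSE)
  }
  if (l2_penalty == 0 && p > 0) {
    prob <- stats::plogis(b0 + as.numeric(Z %*% beta))
    if (all(pmin(prob, 1 - prob) < 1e-8)) {
      stop("perfect separation: unpenalized coefficients are unbounded; ",
           "use a positive l2_penalty", call. = FALSE)
    }
  }
  structure(list(intercept = unname(b0),
                 coefficients = stats::setNames(unname(beta), item_ids),
                 feature_means = stats::setNames(mu, item_ids),
                 feature_scales = stats::setNames(sdv, item_ids),
                 item_ids = item_ids, l2_penalty = l2_penalty,
                 converged = converged, n_iter = it),
            class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf("<fitted_logistic> %d features, intercept %.4f, L2 penalty %g (%d IRLS iterations)\n",
              length(x$coefficients), x$intercept, x$l2_penalty, x$n_iter))
  invisible(x)
}

check_feature_alignment <- function(model, X) {
  X <- as.matrix(X)
  stop_if(ncol(X) != length(model$item_ids),
          "feature matrix width does not match the fitted model")
  if (!is.null(colnames(X)) && length(model$item_ids) > 0 &&
      !identical(colnames(X), model$item_ids)) {
    stop("feature columns do not match the fitted model's item ids",
         call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Linear predictor (log-odds margin) of a fitted logistic model
#'
#' `margin = intercept + sum_j beta_j * (x_j - mean_j) / scale_j`. At the
#' training feature means the margin equals the intercept.
#'
#' @param model a [fit_logistic()] result.
#' @param X feature matrix with columns matching the model's item ids.
#' @return numeric vector of log-odds margins.
#' @export
predict_margin <- function(model, X) {
  stopifnot(inherits(model, "fitted_logistic"))
  X <- check_feature_alignment(model, X)
  if (length(model$item_ids) == 0) return(rep(model$intercept, nrow(X)))
  Z <- sweep(sweep(X, 2L, model$feature_means), 2L, model$feature_scales, "/")
  model$intercept + as.numeric(Z %*% model$coefficients)
}

#' Predicted probabilities (logistic transform of the margin)
#' @inheritParams predict_margin
#' @return numeric vector of probabilities, strictly increasing in the margin.
#' @export
predict_proba <- function(model, X) stats::plogis(predict_margin(model, X))
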