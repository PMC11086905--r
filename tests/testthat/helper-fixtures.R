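# Shared fixtures, built in code.

# small bank with criteria cycling A,B1,B2,B3,B4
tiny_bank <- function(p = 10, reverse = character(0)) {
  ids <- paste0("T-", seq_len(p))
  suppressWarnings(item_bank(data.frame(
    item_id = ids,
    text = paste("synthetic test item", seq_len(p)),
    criterion = rep_len(scs_criteria(), p),
    reverse_coded = ids %in% reverse,
    stringsAsFactors = FALSE
  ), version = "test"))
}

extdata <- function(f) system.file("extdata", f, package = "sfirank")

published_si_ranking <- function() {
  read_ranking_table(extdata("published_ranking_si.csv"), outcome_label = "SI")
}
published_sip_ranking <- function() {
  read_ranking_table(extdata("published_ranking_sip.csv"), outcome_label = "SI_P")
}

# small synthetic cohort for CV tests; outcome driven by factor A only and
# weakly correlated factors so entrapment items carry the recoverable signal
recovery_config <- function(n = 2000, seed = 1L) {
  R <- matrix(0.2, 5, 5); diag(R) <- 1
  synthetic_config(n = n, factor_corr = R,
                   outcome_coeffs_si = c(2, 0, 0, 0, 0),
                   outcome_coeffs_si_p = c(2, 0, 0, 0, 0),
                   target_prev_si = 0.19, target_prev_si_p = 0.05,
                   seed = seed)
}

# reference penalized logistic log-likelihood maximized with optim (L-BFGS-B),
# on standardized features, for cross-checking the IRLS route
ref_penalized_fit <- function(X, y, lambda) {
  Z <- scale(as.matrix(X))
  obj <- function(par) {
    eta <- par[1] + as.numeric(Z %*% par[-1])
    -(sum(y * eta - log1p(exp(eta))) - 0.5 * lambda * sum(par[-1]^2))
  }
  fit <- stats::optim(rep(0, ncol(Z) + 1), obj, method = "L-BFGS-B",
                      control = list(maxit = 1000, factr = 1e3))
  list(par = fit$par, value = -fit$value)
}

# penalized log-likelihood of a fitted_logistic on its own training data
penalized_loglik <- function(model, X, y) {
  eta <- predict_margin(model, X)
  sum(y * eta - log1p(exp(eta))) -
    0.5 * model$l2_penalty * sum(model$coefficients^2)
}
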