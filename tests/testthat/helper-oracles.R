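# Shared fixtures and independent Monte-Carlo / brute-force oracles.

paper_skeleton <- function() calibrate_skeleton(0.2, 0.05, 3, 6)

motivating_truth <- c(0.003, 0.016, 0.047, 0.107, 0.196, 0.305)

# random resolved history on a K-level grid
random_history <- function(n, K = 6, p_dlt = 0.3) {
  trial_history(sample.int(K, n, replace = TRUE),
                stats::rbinom(n, 1, p_dlt))
}

# random history guaranteed to contain both outcome kinds
random_het_history <- function(n, K = 6, p_dlt = 0.3) {
  stopifnot(n >= 2)
  y <- c(1, 0, stats::rbinom(n - 2, 1, p_dlt))
  trial_history(sample.int(K, n, replace = TRUE), sample(y))
}

# self-normalized importance-sampling oracle for the posterior mean and the
# integrated per-level estimates: draws from the prior, weights by the
# likelihood
mc_posterior_oracle <- function(history, skeleton, model, prior,
                                ndraws = 1e5) {
  draws <- switch(prior$family,
    normal = stats::rnorm(ndraws, prior$parameters$mean, prior$parameters$sd),
    unit_exponential = stats::rexp(ndraws, 1),
    stop("oracle supports normal and unit_exponential priors"))
  doses <- working_doses(model, skeleton$probs)
  x <- doses[history$dose_level]
  y <- history$outcome
  lw <- numeric(ndraws)
  for (l in seq_along(x)) {
    psi <- switch(model$family,
      empiric = x[l]^exp(draws),
      logistic1 = stats::plogis(model$intercept + exp(draws) * x[l]))
    lw <- lw + if (y[l] == 1) log(psi) else log1p(-psi)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  mean_a <- sum(w * draws)
  se_mean <- sqrt(sum(w^2 * (draws - mean_a)^2))
  est <- numeric(length(doses)); se_est <- numeric(length(doses))
  for (k in seq_along(doses)) {
    psi <- switch(model$family,
      empiric = doses[k]^exp(draws),
      logistic1 = stats::plogis(model$intercept + exp(draws) * doses[k]))
    est[k] <- sum(w * psi)
    se_est[k] <- sqrt(sum(w^2 * (psi - est[k])^2))
  }
  list(mean_a = mean_a, se_mean = se_mean, est = est, se_est = se_est)
}

# brute-force grid search for the maximum-likelihood estimate
grid_mle_oracle <- function(history, skeleton, model, step = 1e-4) {
  a <- seq(-10, 10, by = step)
  doses <- working_doses(model, skeleton$probs)
  x <- doses[history$dose_level]
  y <- history$outcome
  ll <- numeric(length(a))
  for (l in seq_along(x)) {
    psi <- switch(model$family,
      empiric = x[l]^exp(a),
      logistic1 = stats::plogis(model$intercept + exp(a) * x[l]))
    ll <- ll + if (y[l] == 1) log(psi) else log1p(-psi)
  }
  a[which.max(ll)]
}

# rejection-sampling oracle for the EWOC gamma-marginal CDF under the
# default independent uniform priors
ewoc_rejection_oracle <- function(history, skeleton, ndraws = 2e5) {
  theta <- skeleton$theta
  x <- working_doses(dose_model("logistic2"), skeleton$probs)
  K <- skeleton$K
  rho <- stats::runif(ndraws, 1e-9, theta - 1e-9)
  gam <- stats::runif(ndraws, x[1] + 1e-9, x[K])
  a1 <- (stats::qlogis(theta) - stats::qlogis(rho)) / (gam - x[1])
  a0 <- stats::qlogis(rho) - a1 * x[1]
  ll <- numeric(ndraws)
  for (l in seq_len(nrow(history))) {
    eta <- a0 + a1 * x[history$dose_level[l]]
    ll <- ll + if (history$outcome[l] == 1)
      stats::plogis(eta, log.p = TRUE)
    else stats::plogis(eta, log.p = TRUE, lower.tail = FALSE)
  }
  keep <- stats::runif(ndraws) < exp(ll)   # likelihood is a probability <= 1
  g <- gam[keep]
  cdf <- vapply(x, function(xx) mean(g <= xx), numeric(1))
  se <- sqrt(pmax(cdf * (1 - cdf), 1e-12) / length(g))
  list(cdf = cdf, se = se, n_accepted = length(g), doses = x)
}

# append one resolved record to a history
append_dlt <- function(history, level, y) {
  trial_history(c(history$dose_level, level), c(history$outcome, y),
                c(history$followup, NA))
}
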