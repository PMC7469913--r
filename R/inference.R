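#' Weighted binomial likelihood of a trial history
#'
#' Evaluates
#' \deqn{L(a) = \prod_l [w_l \psi(x_l, a)]^{y_l} [1 - w_l \psi(x_l, a)]^{1-y_l},}
#' the working likelihood of the CRM family. With every weight equal to 1
#' this is the ordinary binomial CRM likelihood; partial weights implement
#' the time-to-event designs. The empty history has likelihood 1.
#'
#' @param history A \code{\link{trial_history}}.
#' @param doses Standardized doses per level (see
#'   \code{\link{working_doses}}).
#' @param model A \code{\link{dose_model}}.
#' @param params Model parameter(s).
#' @param window Observation window; when supplied, weights are recomputed
#'   from the follow-up at every call.
#' @param weights Optional explicit weights overriding the time-to-event
#'   computation.
#' @param log Return the log-likelihood instead.
#' @return A non-negative number (or its log).
#' @export
crm_likelihood <- function(history, doses, model, params,
                           window = NULL, weights = NULL, log = FALSE) {
  n <- nrow(history)
  if (!n) return(if (log) 0 else 1)
  if (any(history$dose_level > length(doses)))
    stop("history refers to a dose level outside the grid")
  if (is.null(weights)) {
    eff <- history_effective(history, window)
  } else {
    if (length(weights) != n || any(weights < 0) || any(weights > 1))
      stop("'weights' must be one value in [0, 1] per record")
    eff <- list(y = ifelse(is.na(history$outcome), 0, history$outcome),
                w = as.numeric(weights))
  }
  x <- doses[history$dose_level]
  psi <- dlt_probability(model, x, params)   # validates the inputs
  # log psi computed on the log scale directly so extreme parameters keep
  # finite log-likelihoods even when psi underflows
  lpsi <- switch(model$family,
    empiric   = exp(params) * base::log(x),
    logistic1 = stats::plogis(model$intercept + exp(params) * x,
                              log.p = TRUE),
    logistic2 = stats::plogis(params[1L] + params[2L] * x, log.p = TRUE))
  ll <- sum(ifelse(eff$y == 1,
                   base::log(eff$w) + lpsi,
                   log1p(-eff$w * psi)))
  if (log) ll else exp(ll)
}

#' Posterior of the model parameter by deterministic quadrature
#'
#' Updates the prior on the one-parameter model by Bayes' theorem,
#' \eqn{f(a \mid \Omega_j) \propto f(a) L(a)}, on a fixed trapezoid grid
#' spanning the prior mean plus/minus \code{span} prior standard deviations
#' (clipped to the prior's support). All likelihood evaluation is done in
#' log space. With an empty history the posterior equals the prior.
#'
#' @param history A \code{\link{trial_history}}.
#' @param skeleton A \code{\link{crm_skeleton}} (or probability vector with
#'   \code{theta} attached via \code{crm_skeleton}).
#' @param model A one-parameter \code{\link{dose_model}}.
#' @param prior A \code{\link{prior_spec}}.
#' @param window Observation window for TITE weighting; \code{NULL} for
#'   complete-observation designs.
#' @param weights Optional explicit per-record weights.
#' @param nodes Number of quadrature nodes (default 2001).
#' @param span Half-width of the grid in prior standard deviations.
#' @return An object of class \code{crm_posterior}: the grid, normalized
#'   density, posterior mean \code{mean_a}, per-level DLT estimates in both
#'   the integrated and plug-in conventions, and a quantile function.
#' @examples
#' sk <- calibrate_skeleton(0.2, 0.05, 3, 6)
#' h <- trial_history(dose_level = 3, outcome = 0)
#' post <- bayes_posterior(h, sk)
#' post$mean_a
#' @export
bayes_posterior <- function(history, skeleton, model = dose_model("empiric"),
                            prior = prior_spec("normal", mean = 0,
                                               sd = sqrt(1.34)),
                            window = NULL, weights = NULL,
                            nodes = 2001L, span = 8) {
  skeleton <- as_skeleton(skeleton)
  if (model$n_params != 1L)
    stop("bayes_posterior handles one-parameter models; see ewoc_posterior")
  doses <- working_doses(model, skeleton$probs)
  grid <- prior_grid(prior, nodes = nodes, span = span)
  qw <- trapezoid_weights(grid)
  lprior <- prior_density(prior, grid, log = TRUE)

  # log-likelihood accumulated per record over the parameter grid
  ll <- numeric(length(grid))
  n <- nrow(history)
  if (n) {
    if (is.null(weights)) {
      eff <- history_effective(history, window)
    } else {
      if (length(weights) != n || any(weights < 0) || any(weights > 1))
        stop("'weights' must be one value in [0, 1] per record")
      eff <- list(y = ifelse(is.na(history$outcome), 0, history$outcome),
                  w = as.numeric(weights))
    }
    for (l in seq_len(n)) {
      # psi over the whole parameter grid for this record's dose
      psi <- switch(model$family,
        empiric   = doses[history$dose_level[l]] ^ exp(grid),
        logistic1 = stats::plogis(model$intercept +
                                    exp(grid) * doses[history$dose_level[l]]))
      p <- eff$w[l] * psi
      ll <- ll + if (eff$y[l] == 1) log(p) else log1p(-p)
    }
  }
  lpost <- lprior + ll
  dens <- exp(lpost - max(lpost))
  Z <- sum(qw * dens)
  if (!is.finite(Z) || Z <= 0)
    stop("posterior failed to normalize (marginal likelihood <= 0)")
  dens <- dens / Z
  mean_a <- sum(qw * grid * dens)

  # per-level estimates: psi on grid for every level
  psi_grid <- switch(model$family,
    empiric   = exp(outer(exp(grid), log(doses))),
    logistic1 = stats::plogis(model$intercept + outer(exp(grid), doses)))
  integrated <- as.numeric(crossprod(psi_grid, qw * dens))
  plugin <- dlt_probability(model, doses, mean_a)

  cdf <- cumsum(qw * dens)
  cdf <- cdf / cdf[length(cdf)]
  qfun <- local({
    g <- grid; cd <- cdf
    function(p) stats::approx(cd, g, xout = p, ties = "ordered",
                              yleft = g[1L], yright = g[length(g)])$y
  })

  structure(
    list(grid = grid, density = dens, quad_weights = qw, mean_a = mean_a,
         dose_estimates = list(integrated = integrated, plugin = plugin),
         quantile = qfun, skeleton = skeleton, model = model, prior = prior,
         n = n),
    class = "crm_posterior")
}

#' @export
print.crm_posterior <- function(x, ...) {
  cat(sprintf("Posterior after %d patient(s): E[a | data] = %.4f\n",
              x$n, x$mean_a))
  est <- rbind(integrated = x$dose_estimates$integrated,
               plugin = x$dose_estimates$plugin)
  colnames(est) <- x$skeleton$labels
  print(round(est, 3))
  invisible(x)
}

#' Per-level DLT probability estimates from a posterior
#'
#' Two conventions are available: \code{integrated} evaluates
#' \eqn{\hat\psi(x_i) = \int \psi(x_i, a) f(a \mid \Omega_j)\,da}, the fully
#' Bayesian estimate; \code{plugin} evaluates \eqn{\psi(x_i, \hat a)} at the
#' posterior mean.
#'
#' @param posterior A \code{crm_posterior} from \code{\link{bayes_posterior}}.
#' @param mode \code{"integrated"} or \code{"plugin"}.
#' @return Numeric vector of estimated DLT probabilities, strictly
#'   increasing across levels.
#' @export
dose_tox_estimates <- function(posterior, mode = c("integrated", "plugin")) {
  stopifnot(inherits(posterior, "crm_posterior"))
  mode <- match.arg(mode)
  posterior$dose_estimates[[mode]]
}

#' Maximum-likelihood estimate of the model parameter
#'
#' Maximizes the (weighted) likelihood over the one free parameter. The
#' likelihood equation has no finite maximizer until the history contains at
#' least one DLT and one non-DLT with positive weight; in that case an error
#' of class \code{crmdose_no_heterogeneity} is raised.
#'
#' @inheritParams bayes_posterior
#' @param lower,upper Search interval for the parameter (default [-10, 10]).
#' @return A list with \code{estimate}, \code{loglik} and
#'   \code{heterogeneity = TRUE}.
#' @export
mle_estimate <- function(history, skeleton, model = dose_model("empiric"),
                         window = NULL, weights = NULL,
                         lower = -10, upper = 10) {
  skeleton <- as_skeleton(skeleton)
  if (model$n_params != 1L)
    stop("mle_estimate handles one-parameter models")
  if (!nrow(history)) stop("cannot maximize the likelihood of an empty history")
  if (is.null(weights)) {
    eff <- history_effective(history, window)
  } else {
    eff <- list(y = ifelse(is.na(history$outcome), 0, history$outcome),
                w = as.numeric(weights))
  }
  act <- eff$w > 0
  if (!any(eff$y[act] == 1) || !any(eff$y[act] == 0))
    stop(errorCondition(
      paste("the likelihood has no maximizer until at least one DLT and one",
            "non-DLT have been observed"),
      class = c("crmdose_no_heterogeneity", "error")))
  doses <- working_doses(model, skeleton$probs)
  nll <- function(a) -crm_likelihood(history, doses, model, a,
                                     window = window, weights = weights,
                                     log = TRUE)
  opt <- stats::optimize(nll, c(lower, upper), tol = 1e-9)
  list(estimate = opt$minimum, loglik = -opt$objective, heterogeneity = TRUE)
}
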