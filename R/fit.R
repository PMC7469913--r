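#' Fit a dose-escalation model to the accumulated trial data
#'
#' The central modelling function: given a design and the history observed
#' so far, computes the parameter estimate (posterior or maximum
#' likelihood), the per-level DLT probability estimates, and the next-dose
#' recommendation with stopping evaluation.
#'
#' @param design A \code{\link{crm_design}}.
#' @param history A \code{\link{trial_history}} (default: empty, in which
#'   case the fit summarizes the prior).
#' @return An object of class \code{crm_fit} with components \code{design},
#'   \code{history}, \code{posterior} (a \code{crm_posterior} or
#'   \code{ewoc_posterior}; NULL during a CRML run-in), \code{mle} (CRML
#'   only), \code{estimates}, and \code{recommendation}. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict} and
#'   \code{plot}.
#' @examples
#' sk <- calibrate_skeleton(0.2, 0.05, 3, 6)
#' d <- crm_design("CRMB", sk, stopping = list(stopping_rule("max_n", n = 25)))
#' f <- crm_fit(d, trial_history(c(3, 4), c(0, 1)))
#' coef(f)
#' predict(f)
#' @export
crm_fit <- function(design, history = trial_history()) {
  stopifnot(inherits(design, "crm_design"))
  is_tite <- design$method %in% c("TITE_CRM", "TITE_EWOC")
  window <- if (is_tite) design$window else NULL
  posterior <- NULL
  mle <- NULL
  estimates <- NULL

  if (design$method %in% c("CRMB", "TITE_CRM")) {
    posterior <- bayes_posterior(history, design$skeleton, design$model,
                                 design$prior, window = window,
                                 nodes = design$nodes)
    estimates <- dose_tox_estimates(posterior, design$estimate)
  } else if (design$method == "CRML") {
    ri <- crml_run_in(history, design$start_level, design$skeleton$K,
                      cohort = design$run_in$cohort)
    if (ri$handoff) {
      mle <- mle_estimate(history, design$skeleton, design$model)
      doses <- working_doses(design$model, design$skeleton$probs)
      estimates <- dlt_probability(design$model, doses, mle$estimate)
    }
  } else {
    posterior <- ewoc_posterior(history, design$skeleton, design$model,
                                priors = design$ewoc_priors, window = window,
                                nodes = design$ewoc_nodes)
    # posterior-mean parameters on the reparameterized scale give the
    # displayed per-level toxicity estimates
    x <- posterior$doses
    a1 <- (stats::qlogis(design$skeleton$theta) -
             stats::qlogis(posterior$mean_rho0)) /
          (posterior$mean_gamma - x[1L])
    a0 <- stats::qlogis(posterior$mean_rho0) - a1 * x[1L]
    estimates <- dlt_probability(design$model, x, c(a0, max(a1, 1e-12)))
  }

  recommendation <- recommend_dose(design, history)
  structure(
    list(design = design, history = history, posterior = posterior,
         mle = mle, estimates = estimates, recommendation = recommendation),
    class = "crm_fit")
}

#' @export
print.crm_fit <- function(x, ...) {
  d <- x$design
  cat(sprintf("%s fit: %d patient(s), target theta = %g\n",
              d$method, nrow(x$history), d$skeleton$theta))
  if (!is.null(x$estimates)) {
    est <- rbind(skeleton = d$skeleton$probs, estimate = x$estimates)
    colnames(est) <- d$skeleton$labels
    print(round(est, 3))
  } else {
    cat("  (algorithmic run-in: no model estimate yet)\n")
  }
  print(x$recommendation)
  invisible(x)
}

#' @export
coef.crm_fit <- function(object, ...) {
  if (!is.null(object$mle)) return(c(a = object$mle$estimate))
  p <- object$posterior
  if (inherits(p, "crm_posterior")) return(c(a = p$mean_a))
  if (inherits(p, "ewoc_posterior"))
    return(c(rho0 = p$mean_rho0, gamma = p$mean_gamma))
  c(a = NA_real_)
}

#' Predicted DLT probabilities per dose level
#'
#' @param object A \code{\link{crm_fit}}.
#' @param levels Level indices (default: all).
#' @param mode Estimate convention for Bayesian CRM fits; defaults to the
#'   design's convention.
#' @param ... Unused.
#' @export
predict.crm_fit <- function(object, levels = NULL, mode = NULL, ...) {
  K <- object$design$skeleton$K
  if (is.null(levels)) levels <- seq_len(K)
  est <- object$estimates
  if (inherits(object$posterior, "crm_posterior") && !is.null(mode))
    est <- dose_tox_estimates(object$posterior, mode)
  if (is.null(est))
    stop("no model estimate available (CRML run-in phase)")
  stats::setNames(est[levels], object$design$skeleton$labels[levels])
}

#' @export
summary.crm_fit <- function(object, ...) {
  h <- object$history
  K <- object$design$skeleton$K
  eff <- tryCatch(
    history_effective(h, if (object$design$method %in%
                             c("TITE_CRM", "TITE_EWOC"))
                           object$design$window else NULL),
    error = function(e) list(y = ifelse(is.na(h$outcome), 0, h$outcome),
                             w = rep(NA_real_, nrow(h))))
  per_dose <- data.frame(
    level = seq_len(K),
    n_treated = as.integer(tabulate(h$dose_level, K)),
    n_dlt = as.integer(tabulate(h$dose_level[!is.na(h$outcome) &
                                               h$outcome == 1L], K)))
  per_dose$obs_rate <- ifelse(per_dose$n_treated > 0,
                              per_dose$n_dlt / per_dose$n_treated, NA_real_)
  per_dose$estimate <- if (is.null(object$estimates)) NA_real_ else
    object$estimates
  out <- list(fit = object, per_dose = per_dose,
              n = nrow(h), n_dlt = sum(eff$y == 1))
  class(out) <- "summary.crm_fit"
  out
}

#' @export
print.summary.crm_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d patient(s), %d DLT(s)\n",
              x$fit$design$method, x$n, x$n_dlt))
  print(x$per_dose, row.names = FALSE)
  print(x$fit$recommendation)
  invisible(x)
}

#' Plot a fitted dose-toxicity curve
#'
#' Draws the skeleton (prior) and the current per-level estimates against
#' dose level, with the target toxicity level as a horizontal reference.
#'
#' @param x A \code{\link{crm_fit}}.
#' @param ... Passed to \code{plot}.
#' @export
plot.crm_fit <- function(x, ...) {
  sk <- x$design$skeleton
  lev <- seq_len(sk$K)
  ylim <- range(0, sk$probs, x$estimates, na.rm = TRUE)
  graphics::plot(lev, sk$probs, type = "b", pch = 1, lty = 2,
                 xlab = "dose level", ylab = "P(DLT)", ylim = ylim, ...)
  if (!is.null(x$estimates))
    graphics::lines(lev, x$estimates, type = "b", pch = 16)
  graphics::abline(h = sk$theta, col = "grey40", lty = 3)
  graphics::legend("topleft", bty = "n", pch = c(1, 16), lty = c(2, 1),
                   legend = c("skeleton (prior)", "current estimate"))
  invisible(x)
}
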