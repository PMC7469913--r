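#' Stopping rule for a dose-finding trial
#'
#' Two rules are supported: \code{max_n} stops inclusions once the maximum
#' sample size is reached, and \code{m_at_level} stops once a predefined
#' number of patients has been treated at the level the design currently
#' recommends (or at a fixed level).
#'
#' @param kind \code{"max_n"} or \code{"m_at_level"}.
#' @param n Maximum sample size (\code{max_n}).
#' @param m Patient-count threshold (\code{m_at_level}).
#' @param level \code{"recommended"} (default) or a fixed level index.
#' @return An object of class \code{stopping_rule}.
#' @export
stopping_rule <- function(kind = c("max_n", "m_at_level"),
                          n = NULL, m = NULL, level = "recommended") {
  kind <- match.arg(kind)
  if (kind == "max_n") {
    if (is.null(n) || n < 1) stop("max_n rule needs n >= 1")
    n <- as.integer(n); m <- NULL; level <- NULL
  } else {
    if (is.null(m) || m < 1) stop("m_at_level rule needs m >= 1")
    m <- as.integer(m); n <- NULL
    if (!identical(level, "recommended")) level <- as.integer(level)
  }
  structure(list(kind = kind, n = n, m = m, level = level),
            class = "stopping_rule")
}

#' Design configuration for a dose-escalation method
#'
#' Bundles everything a design needs to run: the method, the skeleton (which
#' carries the target \eqn{\theta}), the dose-toxicity model, the parameter
#' prior, the EWOC feasibility bound \eqn{\alpha}, the observation window
#' for time-to-event designs, the starting level, the no-skip constraint and
#' the stopping rules.
#'
#' @param method One of \code{"CRMB"}, \code{"CRML"}, \code{"TITE_CRM"},
#'   \code{"EWOC"}, \code{"TITE_EWOC"}.
#' @param skeleton A \code{\link{crm_skeleton}}.
#' @param model A \code{\link{dose_model}}; defaults to empiric for the CRM
#'   family and two-parameter logistic for EWOC.
#' @param prior Parameter prior for the CRM family (default normal with mean
#'   0 and variance 1.34).
#' @param alpha Feasibility bound in (0, 0.5], required for EWOC and
#'   TITE-EWOC: the maximum acceptable posterior probability that an
#'   administered dose exceeds the MTD.
#' @param window Observation window length, required for TITE designs.
#' @param start_level Starting dose level (default: the skeleton's prior MTD
#'   level).
#' @param no_skip Forbid skipping untried levels during escalation
#'   (default TRUE).
#' @param estimate Per-level estimate convention for dose selection:
#'   \code{"integrated"} (default; the posterior-averaged probability) or
#'   \code{"plugin"} (model at the posterior mean).
#' @param stopping List of \code{\link{stopping_rule}}s; at least one
#'   required.
#' @param run_in For CRML: list with \code{cohort} size for the algorithmic
#'   run-in used until the history carries both outcome kinds.
#' @param ewoc_priors For EWOC: list with \code{rho0} and \code{gamma}
#'   \code{\link{prior_spec}}s on the DLT probability at the lowest dose
#'   (support (0, theta)) and on the MTD location (support: the working dose
#'   range); defaults to independent uniforms.
#' @param nodes Quadrature nodes for one-parameter posteriors (default 2001).
#' @param ewoc_nodes Per-axis nodes of the EWOC grid (default 201).
#' @return An object of class \code{crm_design}.
#' @export
crm_design <- function(method = c("CRMB", "CRML", "TITE_CRM", "EWOC",
                                  "TITE_EWOC"),
                       skeleton,
                       model = NULL,
                       prior = prior_spec("normal", mean = 0, sd = sqrt(1.34)),
                       alpha = NULL,
                       window = NULL,
                       start_level = NULL,
                       no_skip = TRUE,
                       estimate = c("integrated", "plugin"),
                       stopping = list(stopping_rule("max_n", n = 25L)),
                       run_in = list(cohort = 1L),
                       ewoc_priors = NULL,
                       nodes = 2001L,
                       ewoc_nodes = 201L) {
  method <- match.arg(method)
  estimate <- match.arg(estimate)
  skeleton <- as_skeleton(skeleton)
  is_ewoc <- method %in% c("EWOC", "TITE_EWOC")
  is_tite <- method %in% c("TITE_CRM", "TITE_EWOC")
  if (is.null(model))
    model <- if (is_ewoc) dose_model("logistic2") else dose_model("empiric")
  if (is_ewoc && model$family != "logistic2")
    stop("EWOC designs use the two-parameter logistic model")
  if (!is_ewoc && model$n_params != 1L)
    stop("CRM designs use a one-parameter model")
  if (is_ewoc) {
    if (is.null(alpha) || alpha <= 0 || alpha > 0.5)
      stop("EWOC designs require a feasibility bound alpha in (0, 0.5]")
  } else if (!is.null(alpha)) {
    stop("'alpha' applies only to EWOC designs")
  }
  if (is_tite) {
    if (is.null(window) || window <= 0)
      stop("TITE designs require a positive observation window")
  }
  if (is.null(start_level)) start_level <- skeleton$nu
  start_level <- as.integer(start_level)
  if (start_level < 1L || start_level > skeleton$K)
    stop("'start_level' must be a valid level index")
  if (!length(stopping) || !all(vapply(stopping, inherits, TRUE,
                                       "stopping_rule")))
    stop("'stopping' must be a non-empty list of stopping_rule objects")
  if (is_ewoc && is.null(ewoc_priors)) {
    doses <- working_doses(model, skeleton$probs)
    ewoc_priors <- list(
      rho0 = prior_spec("uniform", min = 0, max = skeleton$theta),
      gamma = prior_spec("uniform", min = doses[1L],
                         max = doses[skeleton$K]))
  }
  structure(
    list(method = method, skeleton = skeleton, model = model, prior = prior,
         alpha = alpha, window = window, start_level = start_level,
         no_skip = isTRUE(no_skip), estimate = estimate, stopping = stopping,
         run_in = run_in, ewoc_priors = ewoc_priors,
         nodes = as.integer(nodes), ewoc_nodes = as.integer(ewoc_nodes)),
    class = "crm_design")
}

#' @export
print.crm_design <- function(x, ...) {
  cat(sprintf("%s design on %d levels, target theta = %g, start level %d\n",
              x$method, x$skeleton$K, x$skeleton$theta, x$start_level))
  if (!is.null(x$alpha)) cat("  feasibility bound alpha =", x$alpha, "\n")
  if (!is.null(x$window)) cat("  observation window =", x$window, "\n")
  cat("  model:", x$model$family,
      "| estimate:", x$estimate,
      "| no-skip:", x$no_skip, "\n")
  invisible(x)
}

#' CRM dose selection: closest estimate to the target
#'
#' Picks the level whose estimated DLT probability is closest to the target
#' \eqn{\theta}; ties are broken toward the lower (safer) level. With the
#' no-skip constraint the recommendation is capped at one level above the
#' highest level tried so far.
#'
#' @param estimates Per-level estimated DLT probabilities (increasing).
#' @param theta Target toxicity level.
#' @param current_max_tried Highest level administered so far (0 if none).
#' @param no_skip Apply the skip cap.
#' @return A list with \code{level} and \code{constrained_by}
#'   (\code{"none"} or \code{"no_skip"}).
#' @export
crm_next_dose <- function(estimates, theta, current_max_tried = length(estimates),
                          no_skip = TRUE) {
  d <- abs(estimates - theta)
  # ties (within numerical noise) break toward the lower, safer level
  level <- which(d <= min(d) + 1e-10)[1L]
  constrained <- "none"
  if (no_skip) {
    cap <- max(1L, as.integer(current_max_tried) + 1L)
    if (level > cap) { level <- cap; constrained <- "no_skip" }
  }
  list(level = as.integer(level), constrained_by = constrained)
}

#' Algorithmic run-in for likelihood-based CRM
#'
#' Until the history contains both a DLT and a non-DLT, the maximum
#' likelihood estimate does not exist and the trial proceeds
#' algorithmically: starting from \code{start_level}, the dose escalates one
#' level after each cohort free of DLT (never skipping); after the first DLT
#' it remains at the current level. Once both outcome kinds exist, the
#' function signals handoff to model-based selection.
#'
#' @param history A \code{\link{trial_history}} (resolved outcomes only).
#' @param start_level Starting level.
#' @param K Number of levels.
#' @param cohort Cohort size of the run-in (default 1).
#' @return A list with \code{handoff} (logical) and, while
#'   \code{handoff = FALSE}, the next \code{level}.
#' @export
crml_run_in <- function(history, start_level, K, cohort = 1L) {
  if (anyNA(history$outcome))
    stop("the likelihood-based CRM requires resolved outcomes")
  K <- as.integer(K)
  cohort <- as.integer(cohort)
  y <- history$outcome
  if (any(y == 1L) && any(y == 0L))
    return(list(handoff = TRUE, level = NA_integer_))
  lev <- as.integer(start_level)
  n_at <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1L) {
      # first DLT: hold the current level until heterogeneity
      return(list(handoff = FALSE, level = lev))
    }
    n_at <- n_at + 1L
    if (n_at >= cohort) {
      lev <- min(lev + 1L, K)
      n_at <- 0L
    }
  }
  list(handoff = FALSE, level = lev)
}

#' Joint posterior of the EWOC reparameterized pair
#'
#' The two-parameter logistic model is reparameterized as
#' (\eqn{\rho_0}, \eqn{\gamma}): the probability of DLT at the lowest dose
#' and the MTD on the working-dose axis (the dose where the toxicity
#' probability equals \eqn{\theta}). The joint posterior is computed on a
#' fixed 2-D trapezoid grid, \eqn{\rho_0 \in (0, \theta)} and
#' \eqn{\gamma \in [x_1, x_K]}, so the overdose probability
#' \eqn{\pi_j(x) = P(\mathrm{MTD} \le x \mid \Omega_j)} is available as the
#' marginal distribution function of \eqn{\gamma}.
#'
#' @inheritParams bayes_posterior
#' @param priors List with \code{rho0} and \code{gamma}
#'   \code{\link{prior_spec}}s (independent); defaults to uniforms on the
#'   grid supports.
#' @param nodes Per-axis grid size (default 201).
#' @return An object of class \code{ewoc_posterior} with the grids, the
#'   joint density, the \eqn{\gamma} marginal CDF (as a function), the
#'   overdose probabilities \code{pi} at the dose levels, and posterior
#'   means of \eqn{\rho_0} and \eqn{\gamma}.
#' @export
ewoc_posterior <- function(history, skeleton, model = dose_model("logistic2"),
                           priors = NULL, window = NULL, weights = NULL,
                           nodes = 201L) {
  skeleton <- as_skeleton(skeleton)
  if (model$family != "logistic2")
    stop("ewoc_posterior uses the two-parameter logistic model")
  theta <- skeleton$theta
  x <- working_doses(model, skeleton$probs)
  K <- skeleton$K
  if (is.null(priors))
    priors <- list(rho0 = prior_spec("uniform", min = 0, max = theta),
                   gamma = prior_spec("uniform", min = x[1L], max = x[K]))

  eps <- 1e-6
  rho <- seq(eps, theta - eps, length.out = nodes)
  gam <- seq(x[1L], x[K], length.out = nodes)
  gam[1L] <- gam[1L] + 1e-9 * (x[K] - x[1L])   # avoid the degenerate gamma = x1
  wr <- trapezoid_weights(rho)
  wg <- trapezoid_weights(gam)

  # joint grid, rho varying fastest
  R <- rep(rho, times = nodes)
  G <- rep(gam, each = nodes)
  a1 <- (stats::qlogis(theta) - stats::qlogis(R)) / (G - x[1L])
  a0 <- stats::qlogis(R) - a1 * x[1L]
  lp <- prior_density(priors$rho0, R, log = TRUE) +
        prior_density(priors$gamma, G, log = TRUE)

  n <- nrow(history)
  if (n) {
    if (any(history$dose_level > K))
      stop("history refers to a dose level outside the grid")
    if (is.null(weights)) {
      eff <- history_effective(history, window)
    } else {
      eff <- list(y = ifelse(is.na(history$outcome), 0, history$outcome),
                  w = as.numeric(weights))
    }
    for (l in seq_len(n)) {
      eta <- a0 + a1 * x[history$dose_level[l]]
      if (eff$y[l] == 1) {
        lp <- lp + log(eff$w[l]) + stats::plogis(eta, log.p = TRUE)
      } else if (eff$w[l] == 1) {
        lp <- lp + stats::plogis(eta, log.p = TRUE, lower.tail = FALSE)
      } else if (eff$w[l] > 0) {
        lp <- lp + log1p(-eff$w[l] * stats::plogis(eta))
      }
    }
  }
  W <- as.vector(outer(wr, wg))
  d <- exp(lp - max(lp))
  Z <- sum(W * d)
  if (!is.finite(Z) || Z <= 0) stop("EWOC posterior failed to normalize")
  d <- d / Z

  dm <- matrix(d, nodes, nodes)              # rows rho, cols gamma
  gam_marg <- as.numeric(wr %*% dm)          # density of gamma on gam
  rho_marg <- as.numeric(dm %*% wg)
  cdf <- cumsum(c(0, (gam_marg[-1L] + gam_marg[-nodes]) / 2 * diff(gam)))
  cdf <- cdf / cdf[nodes]
  cdf_fun <- local({
    g <- gam; cd <- cdf
    function(xq) stats::approx(g, cd, xout = xq, rule = 2, ties = "ordered")$y
  })
  pi_x <- cdf_fun(x)
  qfun <- local({
    g <- gam; cd <- cdf
    function(p) stats::approx(cd, g, xout = p, ties = "ordered",
                              yleft = g[1L], yright = g[length(g)])$y
  })

  structure(
    list(grid_rho0 = rho, grid_gamma = gam, joint = dm,
         quad_weights = list(rho0 = wr, gamma = wg),
         gamma_cdf = cdf_fun, gamma_quantile = qfun,
         pi = pi_x, doses = x,
         mean_rho0 = sum(wr * rho * rho_marg),
         mean_gamma = sum(wg * gam * gam_marg),
         skeleton = skeleton, theta = theta, n = n),
    class = "ewoc_posterior")
}

#' @export
print.ewoc_posterior <- function(x, ...) {
  cat(sprintf(paste0("EWOC posterior after %d patient(s): ",
                     "E[rho0] = %.3f, E[gamma] = %.3f\n"),
              x$n, x$mean_rho0, x$mean_gamma))
  cat("P(MTD <= x_i):", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' EWOC dose selection under the overdose constraint
#'
#' Recommends the highest level whose overdose probability
#' \eqn{\pi_j(x) = P(\mathrm{MTD} \le x \mid \Omega_j)} does not exceed the
#' feasibility bound \eqn{\alpha}; if no level qualifies, falls back to
#' level 1. The no-skip cap is applied after the overdose control.
#'
#' @param posterior An \code{\link{ewoc_posterior}}.
#' @param alpha Feasibility bound in (0, 0.5].
#' @param current_max_tried Highest level administered so far (0 if none).
#' @param no_skip Apply the skip cap.
#' @return A list with \code{level} and \code{constrained_by}
#'   (\code{"overdose_control"}, \code{"no_skip"} or \code{"none"}).
#' @export
ewoc_next_dose <- function(posterior, alpha, current_max_tried = NULL,
                           no_skip = TRUE) {
  stopifnot(inherits(posterior, "ewoc_posterior"))
  if (alpha <= 0 || alpha > 0.5) stop("'alpha' must be in (0, 0.5]")
  K <- length(posterior$pi)
  if (is.null(current_max_tried)) current_max_tried <- K
  ok <- which(posterior$pi <= alpha + 1e-12)
  if (length(ok)) {
    level <- max(ok)
    constrained <- if (level < K) "overdose_control" else "none"
  } else {
    level <- 1L
    constrained <- "overdose_control"
  }
  if (no_skip) {
    cap <- max(1L, as.integer(current_max_tried) + 1L)
    if (level > cap) { level <- cap; constrained <- "no_skip" }
  }
  list(level = as.integer(level), constrained_by = constrained)
}

#' Evaluate the stopping rules
#'
#' @param history A \code{\link{trial_history}}.
#' @param rules Non-empty list of \code{\link{stopping_rule}}s.
#' @param next_level The level the design would recommend next.
#' @return A list with \code{stop} (logical), the triggering \code{rule}
#'   (or NULL) and a human-readable \code{reason}.
#' @export
check_stopping <- function(history, rules, next_level) {
  if (!length(rules)) stop("'rules' must be non-empty")
  n <- nrow(history)
  for (r in rules) {
    if (r$kind == "max_n" && n >= r$n)
      return(list(stop = TRUE, rule = r,
                  reason = sprintf("maximum sample size %d reached", r$n)))
    if (r$kind == "m_at_level") {
      lev <- if (identical(r$level, "recommended")) next_level else r$level
      treated <- sum(history$dose_level == lev)
      if (treated >= r$m)
        return(list(stop = TRUE, rule = r,
                    reason = sprintf(
                      "%d patients already treated at level %d", treated, lev)))
    }
  }
  list(stop = FALSE, rule = NULL, reason = NA_character_)
}

#' Next-dose recommendation for any design
#'
#' The single entry point used by trial conduct and simulation: fits the
#' design's model to the history, selects the next dose by the method's
#' rule, applies the no-skip constraint, and evaluates the stopping rules.
#' With an empty history the recommendation is the design's starting level.
#'
#' @param design A \code{\link{crm_design}}.
#' @param history A \code{\link{trial_history}}.
#' @return An object of class \code{dose_recommendation}: \code{level},
#'   per-level \code{estimates} (NULL during a CRML run-in),
#'   \code{constrained_by}, \code{stop}, \code{stop_reason}, \code{phase}
#'   (\code{"model"} or \code{"run_in"}).
#' @export
recommend_dose <- function(design, history = trial_history()) {
  stopifnot(inherits(design, "crm_design"))
  K <- design$skeleton$K
  if (nrow(history) && any(history$dose_level > K))
    stop("history refers to a dose level outside the grid")
  is_tite <- design$method %in% c("TITE_CRM", "TITE_EWOC")
  window <- if (is_tite) design$window else NULL

  max_tried <- if (nrow(history)) max(history$dose_level) else 0L
  estimates <- NULL
  phase <- "model"

  if (!nrow(history)) {
    level <- design$start_level
    constrained <- "none"
  } else if (design$method == "CRML") {
    ri <- crml_run_in(history, design$start_level, K,
                      cohort = design$run_in$cohort)
    if (!ri$handoff) {
      phase <- "run_in"
      level <- ri$level
      constrained <- "none"
    } else {
      fit <- mle_estimate(history, design$skeleton, design$model)
      doses <- working_doses(design$model, design$skeleton$probs)
      estimates <- dlt_probability(design$model, doses, fit$estimate)
      sel <- crm_next_dose(estimates, design$skeleton$theta, max_tried,
                           design$no_skip)
      level <- sel$level; constrained <- sel$constrained_by
    }
  } else if (design$method %in% c("CRMB", "TITE_CRM")) {
    post <- bayes_posterior(history, design$skeleton, design$model,
                            design$prior, window = window,
                            nodes = design$nodes)
    estimates <- dose_tox_estimates(post, design$estimate)
    sel <- crm_next_dose(estimates, design$skeleton$theta, max_tried,
                         design$no_skip)
    level <- sel$level; constrained <- sel$constrained_by
  } else {
    post <- ewoc_posterior(history, design$skeleton, design$model,
                           priors = design$ewoc_priors, window = window,
                           nodes = design$ewoc_nodes)
    estimates <- post$pi
    sel <- ewoc_next_dose(post, design$alpha, max_tried, design$no_skip)
    level <- sel$level; constrained <- sel$constrained_by
  }

  st <- check_stopping(history, design$stopping, level)
  structure(
    list(level = as.integer(level), estimates = estimates,
         constrained_by = constrained, phase = phase,
         stop = st$stop, stop_reason = st$reason),
    class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat("Recommended next dose: level", x$level)
  if (x$constrained_by != "none") cat(" (constrained by ", x$constrained_by,
                                      ")", sep = "")
  cat("\n")
  if (x$phase == "run_in") cat("  (algorithmic run-in phase)\n")
  if (!is.null(x$estimates))
    cat("  per-level estimates:",
        paste(sprintf("%.3f", x$estimates), collapse = " "), "\n")
  if (x$stop) cat("  STOP:", x$stop_reason, "\n")
  invisible(x)
}
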