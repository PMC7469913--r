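#' Dose-toxicity model family
#'
#' Defines the parametric family linking a standardized dose to the
#' probability of dose-limiting toxicity (DLT).
#'
#' Three families are supported:
#' \describe{
#'   \item{\code{empiric}}{the power model \eqn{\psi(x, a) = x^{\exp(a)}},
#'     one free parameter; standardized doses live in (0, 1) and are the
#'     skeleton probabilities themselves.}
#'   \item{\code{logistic1}}{one-parameter logistic with fixed intercept
#'     \eqn{b}: \eqn{\psi(x, a) = \mathrm{logit}^{-1}(b + e^{a} x)};
#'     standardized doses are \eqn{\mathrm{logit}(p_i) - b}.}
#'   \item{\code{logistic2}}{two-parameter logistic
#'     \eqn{\psi(x, a) = \mathrm{logit}^{-1}(a_0 + a_1 x)} with slope
#'     \eqn{a_1 > 0}; used by the EWOC designs, where it is handled through
#'     the (\eqn{\rho_0}, \eqn{\gamma}) reparameterization (probability of
#'     DLT at the lowest dose, and maximum tolerated dose).}
#' }
#'
#' @param family Model family, one of \code{"empiric"}, \code{"logistic1"},
#'   \code{"logistic2"}.
#' @param intercept Fixed intercept for \code{logistic1} (default 3, the
#'   common convention for one-parameter logistic CRM).
#' @return An object of class \code{dose_model}.
#' @examples
#' m <- dose_model("empiric")
#' dlt_probability(m, 0.2, 0)      # exp(0) = 1, so psi = x
#' @export
dose_model <- function(family = c("empiric", "logistic1", "logistic2"),
                       intercept = 3) {
  family <- match.arg(family)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("'intercept' must be a single finite number")
  structure(
    list(family = family,
         intercept = if (family == "logistic1") intercept else NULL,
         n_params = if (family == "logistic2") 2L else 1L),
    class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat("Dose-toxicity model:", x$family)
  if (!is.null(x$intercept)) cat(" (fixed intercept ", x$intercept, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Standardized working doses for a model family
#'
#' Maps skeleton probabilities to the model-scale dose values \eqn{x_1 <
#' \dots < x_K} at which the family evaluates. For the empiric family the
#' working doses are the skeleton probabilities; the logistic families use
#' logit-transformed values.
#'
#' @param model A \code{\link{dose_model}}.
#' @param probs Skeleton probabilities, strictly increasing in (0, 1).
#' @return Numeric vector of standardized doses, strictly increasing.
#' @export
working_doses <- function(model, probs) {
  stopifnot(inherits(model, "dose_model"))
  if (any(probs <= 0) || any(probs >= 1))
    stop("skeleton probabilities must lie strictly inside (0, 1)")
  if (any(diff(probs) <= 0))
    stop("skeleton probabilities must be strictly increasing")
  switch(model$family,
    empiric   = probs,
    logistic1 = stats::qlogis(probs) - model$intercept,
    logistic2 = stats::qlogis(probs))
}

#' Probability of DLT under a dose-toxicity model
#'
#' Evaluates \eqn{\psi(x, a)}, the model probability of dose-limiting
#' toxicity at standardized dose \code{x}.
#'
#' @param model A \code{\link{dose_model}}.
#' @param x Standardized dose(s). For the empiric family each value must be
#'   in (0, 1).
#' @param params Parameter vector: a single value \code{a} for the empiric
#'   and one-parameter logistic families; \code{c(a0, a1)} with \code{a1 > 0}
#'   for the two-parameter logistic.
#' @return Probabilities in [0, 1], same length as \code{x}; strictly
#'   increasing in \code{x} for fixed valid parameters.
#' @export
dlt_probability <- function(model, x, params) {
  stopifnot(inherits(model, "dose_model"))
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("'x' must be finite numeric")
  switch(model$family,
    empiric = {
      if (length(params) != 1L) stop("empiric model has exactly one parameter")
      if (any(x <= 0) || any(x >= 1))
        stop("empiric model requires standardized doses in (0, 1)")
      x ^ exp(params)
    },
    logistic1 = {
      if (length(params) != 1L) stop("logistic1 model has exactly one parameter")
      stats::plogis(model$intercept + exp(params) * x)
    },
    logistic2 = {
      if (length(params) != 2L) stop("logistic2 model has two parameters")
      if (!is.finite(params[2L]) || params[2L] <= 0)
        stop("logistic2 slope must be strictly positive")
      stats::plogis(params[1L] + params[2L] * x)
    })
}

#' Construct a skeleton of prior DLT probabilities
#'
#' A skeleton attaches a prior DLT probability to every dose level, together
#' with the target toxicity level \eqn{\theta} and the prior guess of the
#' maximum tolerated dose (level \eqn{\nu}).
#'
#' @param probs Strictly increasing probabilities in (0, 1), one per level.
#' @param theta Target toxicity level in (0, 1).
#' @param nu Prior MTD level index; \code{probs[nu]} should equal
#'   \code{theta} for a calibrated skeleton (enforced up to rounding when
#'   \code{calibrated = TRUE}).
#' @param delta Optional indifference-interval halfwidth used to build the
#'   skeleton (metadata only).
#' @param labels Optional per-level dose labels.
#' @return An object of class \code{crm_skeleton} with fields \code{probs},
#'   \code{theta}, \code{nu}, \code{K}, \code{delta}, \code{labels}.
#' @seealso \code{\link{calibrate_skeleton}}
#' @export
crm_skeleton <- function(probs, theta, nu, delta = NULL, labels = NULL) {
  probs <- as.numeric(probs)
  K <- length(probs)
  if (K < 2L) stop("a skeleton needs at least two dose levels")
  if (any(probs <= 0) || any(probs >= 1))
    stop("skeleton probabilities must lie strictly inside (0, 1)")
  if (any(diff(probs) <= 0))
    stop("skeleton probabilities must be strictly increasing")
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    stop("'theta' must be in (0, 1)")
  nu <- as.integer(nu)
  if (nu < 1L || nu > K) stop("'nu' must be a level index in [1..K]")
  if (is.null(labels)) labels <- paste0("level", seq_len(K))
  structure(
    list(probs = probs, theta = theta, nu = nu, K = K,
         delta = delta, labels = labels),
    class = "crm_skeleton")
}

#' @export
print.crm_skeleton <- function(x, digits = 3, ...) {
  cat(sprintf("Skeleton on %d levels (target theta = %g, prior MTD level %d)\n",
              x$K, x$theta, x$nu))
  print(stats::setNames(round(x$probs, digits), x$labels))
  invisible(x)
}

#' Calibrate a skeleton by the indifference-interval construction
#'
#' Builds the vector of prior DLT probabilities so that level \code{nu} is
#' anchored at the target \eqn{\theta} and adjacent levels are separated by
#' the indifference interval \eqn{[\theta - \delta, \theta + \delta]}: the
#' parameter value that maps level \eqn{i+1} to \eqn{\theta + \delta} maps
#' level \eqn{i} to \eqn{\theta - \delta}.
#'
#' For the empiric family this gives the closed-form recursion
#' \deqn{p_{i+1} = \exp\{\log(\theta+\delta)\,\log(p_i)/\log(\theta-\delta)\}}
#' upward from the anchor and the inverse relation downward. For the
#' one-parameter logistic the boundary conditions are solved on the logit
#' scale.
#'
#' @param theta Target toxicity level in (0, 1).
#' @param delta Halfwidth of the indifference interval,
#'   \code{0 < delta < min(theta, 1 - theta)}.
#' @param nu Prior MTD level index in [1..K].
#' @param K Number of dose levels (>= 2).
#' @param model A \code{\link{dose_model}}; \code{empiric} or
#'   \code{logistic1}.
#' @return A \code{\link{crm_skeleton}}.
#' @examples
#' calibrate_skeleton(theta = 0.2, delta = 0.05, nu = 3, K = 6)
#' @export
calibrate_skeleton <- function(theta, delta, nu, K,
                               model = dose_model("empiric")) {
  stopifnot(inherits(model, "dose_model"))
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    stop("'theta' must be in (0, 1)")
  if (!is.numeric(delta) || delta <= 0 || delta >= min(theta, 1 - theta))
    stop("'delta' must satisfy 0 < delta < min(theta, 1 - theta)")
  K <- as.integer(K); nu <- as.integer(nu)
  if (K < 2L) stop("'K' must be at least 2")
  if (nu < 1L || nu > K) stop("'nu' must be in [1..K]")
  if (model$family == "logistic2")
    stop("skeleton calibration applies to one-parameter families")

  probs <- numeric(K)
  probs[nu] <- theta
  if (model$family == "empiric") {
    lu <- log(theta + delta); ll <- log(theta - delta)
    i <- nu
    while (i < K) { probs[i + 1L] <- exp(lu * log(probs[i]) / ll); i <- i + 1L }
    i <- nu
    while (i > 1L) { probs[i - 1L] <- exp(ll * log(probs[i]) / lu); i <- i - 1L }
  } else {
    # logistic1: on the working-dose scale x = logit(p) - b the boundary
    # conditions are linear, x_{i+1} = x_i * (logit(theta+delta) - b) /
    # (logit(theta-delta) - b), provided the working doses stay negative
    # (probabilities below the intercept's logistic value).
    b <- model$intercept
    hi <- stats::qlogis(theta + delta) - b
    lo <- stats::qlogis(theta - delta) - b
    if (lo >= 0 || hi >= 0)
      stop("intercept too small for the requested target/halfwidth")
    x <- numeric(K)
    x[nu] <- stats::qlogis(theta) - b
    i <- nu
    while (i < K) { x[i + 1L] <- x[i] * hi / lo; i <- i + 1L }
    i <- nu
    while (i > 1L) { x[i - 1L] <- x[i] * lo / hi; i <- i - 1L }
    probs <- stats::plogis(b + x)
  }
  if (any(probs <= 0) || any(probs >= 1) || any(diff(probs) <= 0))
    stop("calibration produced an invalid skeleton; reduce K or delta")
  crm_skeleton(probs, theta = theta, nu = nu, delta = delta)
}

# Coerce a skeleton argument: accept a crm_skeleton or a bare probability
# vector plus theta/nu.
as_skeleton <- function(skeleton, theta = NULL, nu = NULL) {
  if (inherits(skeleton, "crm_skeleton")) return(skeleton)
  if (is.numeric(skeleton)) {
    if (is.null(theta)) stop("'theta' required when skeleton is a bare vector")
    if (is.null(nu)) nu <- which.min(abs(skeleton - theta))
    return(crm_skeleton(skeleton, theta = theta, nu = nu))
  }
  stop("'skeleton' must be a crm_skeleton or a numeric probability vector")
}
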