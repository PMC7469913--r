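#' Prior distribution for a model parameter
#'
#' Specifies the prior placed on the free parameter of a one-parameter
#' dose-toxicity model, or on one coordinate of the EWOC
#' (\eqn{\rho_0}, \eqn{\gamma}) pair.
#'
#' @param family One of \code{"normal"}, \code{"unit_exponential"},
#'   \code{"gamma"}, \code{"uniform"}, \code{"lognormal"}.
#' @param mean,sd Normal parameters (default mean 0, sd \code{sqrt(1.34)},
#'   the usual CRM operational prior).
#' @param shape,rate Gamma parameters.
#' @param min,max Uniform bounds.
#' @param meanlog,sdlog Log-normal parameters.
#' @return An object of class \code{prior_spec}.
#' @examples
#' prior_spec("unit_exponential")   # the f(a) = exp(-a) example prior
#' prior_spec("normal", mean = 0, sd = sqrt(1.34))
#' @export
prior_spec <- function(family = c("normal", "unit_exponential", "gamma",
                                  "uniform", "lognormal"),
                       mean = 0, sd = sqrt(1.34),
                       shape = 1, rate = 1,
                       min = 0, max = 1,
                       meanlog = 0, sdlog = 1) {
  family <- match.arg(family)
  pars <- switch(family,
    normal = {
      if (sd <= 0) stop("normal prior needs sd > 0")
      list(mean = mean, sd = sd)
    },
    unit_exponential = list(),
    gamma = {
      if (shape <= 0 || rate <= 0) stop("gamma prior needs shape, rate > 0")
      list(shape = shape, rate = rate)
    },
    uniform = {
      if (max <= min) stop("uniform prior needs max > min")
      list(min = min, max = max)
    },
    lognormal = {
      if (sdlog <= 0) stop("lognormal prior needs sdlog > 0")
      list(meanlog = meanlog, sdlog = sdlog)
    })
  structure(list(family = family, parameters = pars), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  p <- unlist(x$parameters)
  cat("Prior:", x$family,
      if (length(p)) paste0("(", paste(names(p), p, sep = " = ",
                                       collapse = ", "), ")") else "", "\n")
  invisible(x)
}

prior_density <- function(prior, a, log = FALSE) {
  p <- prior$parameters
  switch(prior$family,
    normal = stats::dnorm(a, p$mean, p$sd, log = log),
    unit_exponential = stats::dexp(a, 1, log = log),
    gamma = stats::dgamma(a, shape = p$shape, rate = p$rate, log = log),
    uniform = stats::dunif(a, p$min, p$max, log = log),
    lognormal = stats::dlnorm(a, p$meanlog, p$sdlog, log = log))
}

prior_mean <- function(prior) {
  p <- prior$parameters
  switch(prior$family,
    normal = p$mean,
    unit_exponential = 1,
    gamma = p$shape / p$rate,
    uniform = (p$min + p$max) / 2,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2))
}

prior_sd <- function(prior) {
  p <- prior$parameters
  switch(prior$family,
    normal = p$sd,
    unit_exponential = 1,
    gamma = sqrt(p$shape) / p$rate,
    uniform = (p$max - p$min) / sqrt(12),
    lognormal = sqrt((exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)))
}

prior_support <- function(prior) {
  p <- prior$parameters
  switch(prior$family,
    normal = c(-Inf, Inf),
    unit_exponential = c(0, Inf),
    gamma = c(0, Inf),
    uniform = c(p$min, p$max),
    lognormal = c(0, Inf))
}

# Quadrature grid covering the prior's effective support:
# mean +/- span prior standard deviations, clipped to the support.
prior_grid <- function(prior, nodes = 2001L, span = 8) {
  sup <- prior_support(prior)
  lo <- max(prior_mean(prior) - span * prior_sd(prior), sup[1L])
  hi <- min(prior_mean(prior) + span * prior_sd(prior), sup[2L])
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("could not build a finite quadrature grid for this prior")
  seq(lo, hi, length.out = nodes)
}

# Trapezoid integration weights for an (arbitrary, sorted) grid.
trapezoid_weights <- function(grid) {
  n <- length(grid)
  h <- diff(grid)
  w <- numeric(n)
  w[1L] <- h[1L] / 2
  w[n] <- h[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (h[-1L] + h[-(n - 1L)]) / 2
  w
}
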