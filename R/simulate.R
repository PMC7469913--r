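#' Simulation scenario
#'
#' The ground truth under which a design is evaluated: the per-level true
#' DLT probabilities, the sample size per trial, and the number of
#' replicates. For time-to-event designs the scenario also carries the
#' accrual model (fixed inter-arrival interval, default one third of the
#' observation window) and the conditional time-to-DLT model (uniform on
#' (0, T], the default).
#'
#' @param true_probs True DLT probability at each level, in [0, 1].
#' @param n Patients per trial.
#' @param n_trials Number of simulated trials.
#' @param accrual_interval Fixed inter-arrival time (TITE designs); default
#'   \code{window / 3} at simulation time.
#' @param dlt_time Conditional time-to-DLT model; only \code{"uniform"} is
#'   provided.
#' @return An object of class \code{trial_scenario}.
#' @export
trial_scenario <- function(true_probs, n = 25L, n_trials = 1000L,
                           accrual_interval = NULL,
                           dlt_time = c("uniform")) {
  dlt_time <- match.arg(dlt_time)
  true_probs <- as.numeric(true_probs)
  if (any(true_probs < 0) || any(true_probs > 1))
    stop("'true_probs' must be probabilities")
  if (any(diff(true_probs) < 0))
    warning("'true_probs' is not nondecreasing across levels")
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  structure(list(true_probs = true_probs, n = as.integer(n),
                 n_trials = as.integer(n_trials),
                 accrual_interval = accrual_interval, dlt_time = dlt_time),
            class = "trial_scenario")
}

# ---- precomputed engines: same estimators as the public path, with the ----
# ---- per-design quantities (grids, psi matrices) built once per batch  ----

crm_engine <- function(design) {
  sk <- design$skeleton
  doses <- working_doses(design$model, sk$probs)
  grid <- prior_grid(design$prior, nodes = design$nodes)
  qw <- trapezoid_weights(grid)
  lprior <- prior_density(design$prior, grid, log = TRUE)
  lpsi <- switch(design$model$family,
    empiric   = outer(exp(grid), log(doses)),
    logistic1 = stats::plogis(design$model$intercept + outer(exp(grid), doses),
                              log.p = TRUE))
  psi <- exp(lpsi)
  l1m <- log1p(-psi)
  plugin_fun <- function(a) dlt_probability(design$model, doses, a)
  list(kind = "crm", grid = grid, qw = qw, lprior = lprior,
       lpsi = lpsi, psi = psi, l1m = l1m, doses = doses,
       theta = sk$theta, K = sk$K, estimate = design$estimate,
       plugin_fun = plugin_fun)
}

# counts path (every weight 1): nD/nN are per-level DLT / non-DLT counts
crm_engine_estimates <- function(eng, nD, nN) {
  ll <- as.vector(eng$lpsi %*% nD + eng$l1m %*% nN)
  d <- exp(eng$lprior + ll - max(eng$lprior + ll))
  d <- d / sum(eng$qw * d)
  if (eng$estimate == "plugin") {
    eng$plugin_fun(sum(eng$qw * eng$grid * d))
  } else {
    as.numeric(crossprod(eng$psi, eng$qw * d))
  }
}

# weighted path (TITE): per-record levels, outcomes, weights
crm_engine_estimates_w <- function(eng, levels, y, w) {
  ll <- numeric(length(eng$grid))
  for (l in seq_along(levels)) {
    p <- w[l] * eng$psi[, levels[l]]
    ll <- ll + if (y[l] == 1) log(p) else log1p(-p)
  }
  d <- exp(eng$lprior + ll - max(eng$lprior + ll))
  d <- d / sum(eng$qw * d)
  if (eng$estimate == "plugin") {
    eng$plugin_fun(sum(eng$qw * eng$grid * d))
  } else {
    as.numeric(crossprod(eng$psi, eng$qw * d))
  }
}

ewoc_engine <- function(design) {
  sk <- design$skeleton
  theta <- sk$theta
  x <- working_doses(design$model, sk$probs)
  nodes <- design$ewoc_nodes
  eps <- 1e-6
  rho <- seq(eps, theta - eps, length.out = nodes)
  gam <- seq(x[1L], x[sk$K], length.out = nodes)
  gam[1L] <- gam[1L] + 1e-9 * (x[sk$K] - x[1L])
  wr <- trapezoid_weights(rho)
  wg <- trapezoid_weights(gam)
  R <- rep(rho, times = nodes)
  G <- rep(gam, each = nodes)
  a1 <- (stats::qlogis(theta) - stats::qlogis(R)) / (G - x[1L])
  a0 <- stats::qlogis(R) - a1 * x[1L]
  eta <- outer(a0, rep(1, sk$K)) + outer(a1, rep(1, sk$K)) *
    matrix(x, nodes * nodes, sk$K, byrow = TRUE)
  lpsi <- stats::plogis(eta, log.p = TRUE)
  l1m <- stats::plogis(eta, log.p = TRUE, lower.tail = FALSE)
  lp0 <- prior_density(design$ewoc_priors$rho0, R, log = TRUE) +
         prior_density(design$ewoc_priors$gamma, G, log = TRUE)
  list(kind = "ewoc", nodes = nodes, gam = gam, wr = wr, wg = wg,
       lpsi = lpsi, l1m = l1m, psi = exp(lpsi), lp0 = lp0, x = x,
       alpha = design$alpha, K = sk$K)
}

ewoc_engine_level <- function(eng, ll) {
  lp <- eng$lp0 + ll
  d <- exp(lp - max(lp))
  dm <- matrix(d, eng$nodes, eng$nodes)
  gm <- as.numeric(eng$wr %*% dm)
  cdf <- cumsum(c(0, (gm[-1L] + gm[-eng$nodes]) / 2 * diff(eng$gam)))
  cdf <- cdf / cdf[eng$nodes]
  pi_x <- stats::approx(eng$gam, cdf, xout = eng$x, rule = 2,
                        ties = "ordered")$y
  ok <- which(pi_x <= eng$alpha + 1e-12)
  if (length(ok)) max(ok) else 1L
}

#' Simulate one trial under a design and scenario
#'
#' Runs the design patient by patient: each patient is treated at the
#' current recommendation (starting level first), the outcome is drawn
#' Bernoulli from the scenario's true probability at the treated level, and
#' the recommendation is recomputed. Complete-observation designs resolve
#' each outcome before the next enrollment; TITE designs enroll on the
#' accrual clock with weights from the elapsed follow-up, and the final
#' recommendation uses the fully observed data.
#'
#' @param design A \code{\link{crm_design}}.
#' @param scenario A \code{\link{trial_scenario}}.
#' @param seed Integer seed for this trial.
#' @param engine Internal precomputed engine (built automatically).
#' @return A list with \code{mtd} (final recommended level),
#'   \code{n_per_level}, \code{dlt_per_level}, \code{n}, \code{n_dlt} and
#'   the realized \code{history}.
#' @export
run_single_trial <- function(design, scenario, seed,
                             engine = NULL) {
  stopifnot(inherits(design, "crm_design"),
            inherits(scenario, "trial_scenario"))
  K <- design$skeleton$K
  if (length(scenario$true_probs) != K)
    stop("scenario and design disagree on the number of levels")
  set.seed(as.integer(seed))
  is_tite <- design$method %in% c("TITE_CRM", "TITE_EWOC")
  if (is_tite) return(run_single_trial_tite(design, scenario, engine))

  if (is.null(engine)) engine <- build_engine(design)
  nD <- numeric(K); nN <- numeric(K)
  levels_given <- integer(scenario$n); outcomes <- integer(scenario$n)
  lev <- design$start_level
  max_tried <- 0L
  n <- 0L
  repeat {
    n <- n + 1L
    y <- stats::runif(1) < scenario$true_probs[lev]
    levels_given[n] <- lev; outcomes[n] <- as.integer(y)
    if (y) nD[lev] <- nD[lev] + 1 else nN[lev] <- nN[lev] + 1
    max_tried <- max(max_tried, lev)
    r <- next_level_engine(design, engine, nD, nN, levels_given[seq_len(n)],
                           outcomes[seq_len(n)])
    if (design$no_skip) r <- min(r, max_tried + 1L)
    stop_now <- n >= scenario$n ||
      check_stopping(trial_history(levels_given[seq_len(n)],
                                   outcomes[seq_len(n)]),
                     design$stopping, r)$stop
    lev <- r
    if (stop_now) break
  }
  list(mtd = as.integer(lev),
       n_per_level = as.integer(tabulate(levels_given[seq_len(n)], K)),
       dlt_per_level = as.integer(tabulate(
         levels_given[seq_len(n)][outcomes[seq_len(n)] == 1L], K)),
       n = n, n_dlt = sum(outcomes[seq_len(n)]),
       history = trial_history(levels_given[seq_len(n)],
                               outcomes[seq_len(n)]))
}

build_engine <- function(design) {
  if (design$method %in% c("EWOC", "TITE_EWOC")) ewoc_engine(design)
  else if (design$method %in% c("CRMB", "TITE_CRM")) crm_engine(design)
  else crm_engine(design)  # CRML uses the model only after run-in
}

# next level from sufficient statistics (complete observations)
next_level_engine <- function(design, engine, nD, nN, levels, outcomes) {
  if (design$method == "CRML") {
    h <- trial_history(levels, outcomes)
    ri <- crml_run_in(h, design$start_level, design$skeleton$K,
                      cohort = design$run_in$cohort)
    if (!ri$handoff) return(ri$level)
    fit <- mle_estimate(h, design$skeleton, design$model)
    est <- dlt_probability(design$model, engine$doses, fit$estimate)
    return(crm_next_dose(est, design$skeleton$theta,
                         no_skip = FALSE)$level)
  }
  if (engine$kind == "crm") {
    est <- crm_engine_estimates(engine, nD, nN)
    crm_next_dose(est, design$skeleton$theta, no_skip = FALSE)$level
  } else {
    ll <- as.vector(engine$lpsi %*% nD + engine$l1m %*% nN)
    ewoc_engine_level(engine, ll)
  }
}

#' Simulate the per-patient timeline of a TITE trial
#'
#' Given the treated levels, draws arrival times on a fixed accrual clock,
#' the DLT indicator at each patient's level, and (conditional on a DLT) a
#' uniform time to DLT inside the observation window.
#'
#' @param scenario A \code{\link{trial_scenario}}.
#' @param levels Treated level per patient.
#' @param window Observation window length.
#' @return Data frame with \code{arrival}, \code{dlt}, \code{dlt_time}
#'   (NA when no DLT).
#' @export
simulate_tite_timeline <- function(scenario, levels, window) {
  stopifnot(inherits(scenario, "trial_scenario"))
  gap <- if (is.null(scenario$accrual_interval)) window / 3
         else scenario$accrual_interval
  n <- length(levels)
  arrival <- (seq_len(n) - 1L) * gap
  dlt <- stats::runif(n) < scenario$true_probs[levels]
  dlt_time <- ifelse(dlt, stats::runif(n, 0, window), NA_real_)
  dlt_time[dlt & dlt_time == 0] <- window * 1e-9  # support is (0, T]
  data.frame(arrival = arrival, dlt = dlt, dlt_time = dlt_time)
}

run_single_trial_tite <- function(design, scenario, engine = NULL) {
  if (is.null(engine)) engine <- build_engine(design)
  K <- design$skeleton$K
  Tw <- design$window
  gap <- if (is.null(scenario$accrual_interval)) Tw / 3
         else scenario$accrual_interval
  n <- scenario$n
  levels_given <- integer(n); dlt <- logical(n); dlt_time <- numeric(n)
  lev <- design$start_level
  max_tried <- 0L
  for (j in seq_len(n)) {
    if (j > 1L) {
      now <- (j - 1L) * gap
      prev <- seq_len(j - 1L)
      elapsed <- pmin(now - (prev - 1L) * gap, Tw)
      y <- as.integer(dlt[prev] & dlt_time[prev] <= elapsed)
      u <- ifelse(y == 1L, dlt_time[prev], elapsed)
      w <- ifelse(y == 1L, 1, u / Tw)
      r <- if (engine$kind == "crm") {
        est <- crm_engine_estimates_w(engine, levels_given[prev], y, w)
        crm_next_dose(est, design$skeleton$theta, no_skip = FALSE)$level
      } else {
        ll <- numeric(engine$nodes^2)
        for (l in prev) {
          if (y[l] == 1L) ll <- ll + engine$lpsi[, levels_given[l]]
          else if (w[l] > 0)
            ll <- ll + log1p(-w[l] * engine$psi[, levels_given[l]])
        }
        ewoc_engine_level(engine, ll)
      }
      if (design$no_skip) r <- min(r, max_tried + 1L)
      lev <- r
    }
    levels_given[j] <- lev
    max_tried <- max(max_tried, lev)
    dlt[j] <- stats::runif(1) < scenario$true_probs[lev]
    dlt_time[j] <- if (dlt[j]) max(stats::runif(1, 0, Tw), Tw * 1e-9)
                   else NA_real_
  }
  # final recommendation from complete follow-up
  y <- as.integer(dlt)
  final <- if (engine$kind == "crm") {
    est <- crm_engine_estimates_w(engine, levels_given, y, rep(1, n))
    crm_next_dose(est, design$skeleton$theta, no_skip = FALSE)$level
  } else {
    ll <- numeric(engine$nodes^2)
    for (l in seq_len(n)) {
      ll <- ll + if (y[l] == 1L) engine$lpsi[, levels_given[l]]
                 else engine$l1m[, levels_given[l]]
    }
    ewoc_engine_level(engine, ll)
  }
  if (design$no_skip) final <- min(final, max_tried + 1L)
  list(mtd = as.integer(final),
       n_per_level = as.integer(tabulate(levels_given, K)),
       dlt_per_level = as.integer(tabulate(levels_given[dlt], K)),
       n = n, n_dlt = sum(dlt),
       history = trial_history(levels_given, y,
                               rep(Tw, n)))
}

#' Monte-Carlo operating characteristics of a design
#'
#' Replicates \code{\link{run_single_trial}} over independent per-trial seed
#' substreams derived from one root seed (so results do not depend on
#' execution order) and aggregates: the distribution of the recommended MTD
#' across trials, the average number of patients treated per level, the
#' average DLT count, and the fractions of patients treated below, at and
#' above the level whose true toxicity is closest to the target.
#'
#' @param design A \code{\link{crm_design}}.
#' @param scenario A \code{\link{trial_scenario}}.
#' @param seed Root seed.
#' @return An object of class \code{crm_oc} with fields \code{mtd_dist},
#'   \code{avg_patients}, \code{avg_dlts}, \code{pct_under}, \code{pct_at},
#'   \code{pct_over}, \code{true_mtd_level}, \code{n_trials}.
#' @examples
#' sk <- calibrate_skeleton(0.2, 0.05, 3, 6)
#' d <- crm_design("CRMB", sk, stopping = list(stopping_rule("max_n", n = 12)))
#' sc <- trial_scenario(c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), n = 12,
#'                      n_trials = 10)
#' run_batch(d, sc, seed = 1)
#' @export
run_batch <- function(design, scenario, seed = 1L) {
  stopifnot(inherits(design, "crm_design"),
            inherits(scenario, "trial_scenario"))
  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, scenario$n_trials)
  engine <- build_engine(design)
  K <- design$skeleton$K
  mtd <- integer(scenario$n_trials)
  npl <- matrix(0L, scenario$n_trials, K)
  dpl <- matrix(0L, scenario$n_trials, K)
  nd <- integer(scenario$n_trials)
  nn <- integer(scenario$n_trials)
  for (i in seq_len(scenario$n_trials)) {
    r <- run_single_trial(design, scenario, seed = subseeds[i],
                          engine = engine)
    mtd[i] <- r$mtd; npl[i, ] <- r$n_per_level; dpl[i, ] <- r$dlt_per_level
    nd[i] <- r$n_dlt; nn[i] <- r$n
  }
  true_mtd <- which.min(abs(scenario$true_probs - design$skeleton$theta))
  tot <- colSums(npl)
  structure(
    list(mtd_dist = as.numeric(table(factor(mtd, levels = seq_len(K))) /
                                 scenario$n_trials),
         avg_patients = colMeans(npl),
         avg_dlts = mean(nd),
         mtd_counts = as.integer(table(factor(mtd, levels = seq_len(K)))),
         pct_under = sum(tot[seq_len(true_mtd - 1L)]) / sum(tot),
         pct_at = tot[true_mtd] / sum(tot),
         pct_over = if (true_mtd < K)
           sum(tot[(true_mtd + 1L):K]) / sum(tot) else 0,
         true_mtd_level = true_mtd,
         avg_n = mean(nn),
         n_trials = scenario$n_trials,
         scenario = scenario, method = design$method),
    class = "crm_oc")
}

#' @export
print.crm_oc <- function(x, digits = 3, ...) {
  cat(sprintf("%s operating characteristics over %d simulated trials\n",
              x$method, x$n_trials))
  tab <- data.frame(level = seq_along(x$mtd_dist),
                    true_prob = x$scenario$true_probs,
                    mtd_pct = round(100 * x$mtd_dist, 1),
                    avg_patients = round(x$avg_patients, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("mean DLTs per trial: %.2f; treated under/at/over true MTD: %.1f%% / %.1f%% / %.1f%%\n",
              x$avg_dlts, 100 * x$pct_under, 100 * x$pct_at,
              100 * x$pct_over))
  invisible(x)
}

#' @export
as.data.frame.crm_oc <- function(x, ...) {
  data.frame(level = seq_along(x$mtd_dist),
             true_prob = x$scenario$true_probs,
             mtd_fraction = x$mtd_dist,
             avg_patients = x$avg_patients)
}

#' @export
plot.crm_oc <- function(x, ...) {
  graphics::barplot(100 * x$mtd_dist, names.arg = seq_along(x$mtd_dist),
                    xlab = "dose level", ylab = "% of trials recommending",
                    ...)
  invisible(x)
}

#' Simulate trials from a design (S3 method)
#'
#' Convenience wrapper calling \code{\link{run_single_trial}} \code{nsim}
#' times with seeds derived from \code{seed}.
#'
#' @param object A \code{\link{crm_design}}.
#' @param nsim Number of trials.
#' @param seed Root seed.
#' @param scenario A \code{\link{trial_scenario}} (its \code{n_trials} is
#'   ignored in favor of \code{nsim}).
#' @param ... Unused.
#' @return List of per-trial results.
#' @export
simulate.crm_design <- function(object, nsim = 1, seed = NULL,
                                scenario, ...) {
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, nsim)
  engine <- build_engine(object)
  lapply(subseeds, function(s)
    run_single_trial(object, scenario, seed = s, engine = engine))
}
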