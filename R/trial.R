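TRIAL_SCHEMA_VERSION <- 1L

audit_entry <- function(action, payload = list()) {
  list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       action = action, payload = payload)
}

#' Open a new trial under a design
#'
#' Creates the stateful trial object used for real-time conduct. The design
#' (skeleton, model, priors, stopping rules) is frozen as soon as the first
#' patient is included.
#'
#' @param design A \code{\link{crm_design}}.
#' @param name Optional study name.
#' @return An object of class \code{crm_trial} with status \code{"setup"}.
#' @export
trial_start <- function(design, name = "study") {
  stopifnot(inherits(design, "crm_design"))
  structure(
    list(design = design, name = name, history = trial_history(),
         recommendations = data.frame(patient = integer(),
                                      recommended = integer(),
                                      administered = integer()),
         status = "setup",
         audit = list(audit_entry("init", list(name = name,
                                               method = design$method))),
         schema_version = TRIAL_SCHEMA_VERSION),
    class = "crm_trial")
}

# the recommendation that stood before a new inclusion
current_recommendation <- function(trial) {
  if (trial$status == "stopped")
    stop("the trial is stopped; no further inclusions")
  recommend_dose(trial$design, trial$history)
}

recompute_after_change <- function(trial, action, payload) {
  rec <- tryCatch(recommend_dose(trial$design, trial$history),
                  error = function(e) e)
  if (inherits(rec, "error")) {
    trial$next_recommendation <- NULL
    trial$pending_block <- conditionMessage(rec)
  } else {
    trial$next_recommendation <- rec
    trial$pending_block <- NULL
    if (rec$stop) trial$status <- "stopped"
  }
  trial$audit <- c(trial$audit, list(audit_entry(action, payload)))
  trial
}

#' Include a new patient
#'
#' Appends a patient record, moves the trial from \code{setup} to
#' \code{open} on the first inclusion, recomputes the model recommendation
#' and evaluates the stopping rules. The clinician may administer a level
#' other than the recommended one; both are recorded.
#'
#' @param trial A \code{\link{trial_start}} object with status
#'   \code{setup} or \code{open}.
#' @param outcome 0, 1 or \code{NA}/\code{"pending"}.
#' @param dose_level Administered level; default: the current
#'   recommendation.
#' @param followup Follow-up time (TITE designs); must not exceed the
#'   observation window.
#' @return The updated \code{crm_trial}; the new recommendation is in
#'   \code{$next_recommendation}.
#' @export
include_patient <- function(trial, outcome, dose_level = NULL,
                            followup = NULL) {
  stopifnot(inherits(trial, "crm_trial"))
  if (trial$status == "stopped")
    stop("the trial is stopped; no further inclusions")
  K <- trial$design$skeleton$K
  is_tite <- trial$design$method %in% c("TITE_CRM", "TITE_EWOC")
  rec <- tryCatch(recommend_dose(trial$design, trial$history),
                  error = function(e) e)
  if (inherits(rec, "error")) {
    # non-TITE design with unresolved outcomes: no model recommendation
    if (is.null(dose_level)) stop(conditionMessage(rec))
    rec <- list(level = NA_integer_)
  }
  if (is.null(dose_level)) dose_level <- rec$level
  dose_level <- as.integer(dose_level)
  if (dose_level < 1L || dose_level > K)
    stop(sprintf("dose level %d outside the %d-level grid", dose_level, K))
  if (is.character(outcome) && outcome %in% c("pending", "p"))
    outcome <- NA_integer_
  outcome <- suppressWarnings(as.integer(outcome))
  if (!is.na(outcome) && !(outcome %in% 0:1))
    stop("outcome must be 0, 1 or pending")
  if (is.null(followup))
    followup <- if (is_tite && !is.na(outcome)) trial$design$window
                else NA_real_
  if (!is.null(trial$design$window) && !is.na(followup) &&
      followup > trial$design$window)
    stop("follow-up cannot exceed the observation window")
  if (is.na(outcome) && !is.na(followup) && !is.null(trial$design$window) &&
      followup >= trial$design$window)
    stop("a pending outcome requires follow-up strictly below the window")

  trial$history <- append_record(trial$history, dose_level, outcome, followup)
  trial$recommendations <- rbind(
    trial$recommendations,
    data.frame(patient = nrow(trial$history), recommended = rec$level,
               administered = dose_level))
  if (trial$status == "setup") trial$status <- "open"
  recompute_after_change(trial, "include",
                         list(id = nrow(trial$history), dose = dose_level,
                              outcome = outcome, followup = followup,
                              recommended = rec$level))
}

#' Resolve or advance a pending patient
#'
#' Updates a pending record once the DLT response is known, or advances the
#' follow-up of an incomplete observation (TITE designs). Follow-up can only
#' increase; resolved records require \code{\link{modify_patient}}.
#'
#' @param trial A \code{crm_trial}.
#' @param id Patient id.
#' @param outcome New outcome (0/1), or \code{NA} to only advance follow-up.
#' @param followup New follow-up time (must be >= the recorded one).
#' @return The updated trial.
#' @export
update_pending <- function(trial, id, outcome = NA, followup = NULL) {
  stopifnot(inherits(trial, "crm_trial"))
  id <- as.integer(id)
  if (!id %in% trial$history$id) stop("unknown patient id ", id)
  i <- which(trial$history$id == id)
  if (!is.na(trial$history$outcome[i]) )
    stop("patient ", id, " is already resolved; use modify_patient")
  if (is.character(outcome) && outcome %in% c("pending", "p"))
    outcome <- NA_integer_
  outcome <- suppressWarnings(as.integer(outcome))
  if (!is.null(followup)) {
    old <- trial$history$followup[i]
    if (!is.na(old) && followup < old)
      stop("follow-up cannot decrease (", old, " -> ", followup, ")")
    if (!is.null(trial$design$window) && followup > trial$design$window)
      stop("follow-up cannot exceed the observation window")
    trial$history$followup[i] <- followup
  }
  if (!is.na(outcome)) {
    trial$history$outcome[i] <- outcome
    if (outcome == 0L && is.null(followup) &&
        !is.null(trial$design$window))
      trial$history$followup[i] <- trial$design$window
  }
  recompute_after_change(trial, "update",
                         list(id = id, outcome = outcome,
                              followup = trial$history$followup[i]))
}

#' Correct a patient record
#'
#' Explicit data correction: replaces fields of an existing record and
#' recomputes the whole recommendation history from scratch (replay). A
#' reason is mandatory and is written to the audit trail.
#'
#' @param trial A \code{crm_trial}.
#' @param id Patient id.
#' @param dose_level,outcome,followup Fields to replace (NULL = keep).
#' @param reason Mandatory justification for the audit trail.
#' @return The updated trial.
#' @export
modify_patient <- function(trial, id, dose_level = NULL, outcome = NULL,
                           followup = NULL, reason) {
  stopifnot(inherits(trial, "crm_trial"))
  if (missing(reason) || !nzchar(reason))
    stop("a correction requires an explicit 'reason'")
  id <- as.integer(id)
  if (!id %in% trial$history$id) stop("unknown patient id ", id)
  i <- which(trial$history$id == id)
  if (!is.null(dose_level)) {
    dose_level <- as.integer(dose_level)
    if (dose_level < 1L || dose_level > trial$design$skeleton$K)
      stop("corrected dose level outside the grid")
    trial$history$dose_level[i] <- dose_level
  }
  if (!is.null(outcome)) {
    if (is.character(outcome) && outcome %in% c("pending", "p"))
      outcome <- NA_integer_
    outcome <- suppressWarnings(as.integer(outcome))
    if (!is.na(outcome) && !(outcome %in% 0:1))
      stop("outcome must be 0, 1 or pending")
    trial$history$outcome[i] <- outcome
  }
  if (!is.null(followup)) {
    if (!is.null(trial$design$window) && followup > trial$design$window)
      stop("follow-up cannot exceed the observation window")
    trial$history$followup[i] <- followup
  }
  # deterministic replay of the whole recommendation sequence
  trial$recommendations <- replay_recommendations(trial$design, trial$history,
                                                  trial$recommendations)
  recompute_after_change(trial, "modify",
                         list(id = id, reason = reason))
}

# Recompute the recommendation that preceded each inclusion from the raw
# history; administered levels are preserved.
replay_recommendations <- function(design, history, recommendations) {
  n <- nrow(history)
  recs <- integer(n)
  for (j in seq_len(n)) {
    sub <- history[seq_len(j - 1L), , drop = FALSE]
    class(sub) <- c("crm_history", "data.frame")
    r <- tryCatch(recommend_dose(design, sub), error = function(e) NULL)
    recs[j] <- if (is.null(r)) NA_integer_ else r$level
  }
  data.frame(patient = seq_len(n), recommended = recs,
             administered = history$dose_level)
}

#' Batch inclusion of several patients
#'
#' Enters several patient records at once (time-to-event designs, where
#' accrual is continuous). The rows are validated first and applied in
#' order; any malformed row aborts the whole batch, leaving the trial
#' unchanged.
#'
#' @param trial A \code{crm_trial} under a TITE design.
#' @param rows Data frame with columns \code{dose_level}, \code{outcome},
#'   \code{followup}.
#' @return The updated trial, equivalent to sequential
#'   \code{\link{include_patient}} calls.
#' @export
batch_include <- function(trial, rows) {
  stopifnot(inherits(trial, "crm_trial"))
  if (!trial$design$method %in% c("TITE_CRM", "TITE_EWOC"))
    stop("batch inclusion is available for time-to-event designs")
  need <- c("dose_level", "outcome", "followup")
  if (!all(need %in% names(rows)))
    stop("rows need columns dose_level, outcome, followup")
  # validate everything before touching the state (atomicity)
  probe <- trial
  out <- tryCatch({
    for (r in seq_len(nrow(rows)))
      probe <- include_patient(probe, outcome = rows$outcome[r],
                               dose_level = rows$dose_level[r],
                               followup = rows$followup[r])
    probe
  }, error = function(e) e)
  if (inherits(out, "error"))
    stop("batch rejected, state unchanged: ", conditionMessage(out))
  out
}

#' The standing next-dose recommendation of a trial
#'
#' @param trial A \code{crm_trial}.
#' @return A \code{dose_recommendation}. Errors if the design requires
#'   resolved outcomes and some are pending.
#' @export
next_dose <- function(trial) {
  stopifnot(inherits(trial, "crm_trial"))
  if (!is.null(trial$pending_block)) stop(trial$pending_block)
  if (is.null(trial$next_recommendation))
    return(recommend_dose(trial$design, trial$history))
  trial$next_recommendation
}

#' Freeze check: the design of an open trial is immutable
#'
#' @param trial A \code{crm_trial}.
#' @param design Replacement design.
#' @return The trial with the new design (only while status is
#'   \code{"setup"}).
#' @export
replace_design <- function(trial, design) {
  stopifnot(inherits(trial, "crm_trial"), inherits(design, "crm_design"))
  if (trial$status != "setup")
    stop("the study parameters can no longer be modified after the first ",
         "patient is included")
  trial$design <- design
  trial$audit <- c(trial$audit, list(audit_entry("replace_design", list())))
  trial
}

#' @export
print.crm_trial <- function(x, ...) {
  cat(sprintf("Trial '%s' (%s): %d patient(s), status %s\n",
              x$name, x$design$method, nrow(x$history), x$status))
  if (!is.null(x$next_recommendation)) print(x$next_recommendation)
  if (!is.null(x$pending_block))
    cat("  model recommendation blocked:", x$pending_block, "\n")
  invisible(x)
}

#' Summarize a trial per patient, per dose, and as a trajectory
#'
#' @param object A \code{crm_trial}.
#' @param ... Unused.
#' @return A list of class \code{summary.crm_trial} with \code{per_patient},
#'   \code{per_dose} and \code{trajectory} data frames.
#' @export
summary.crm_trial <- function(object, ...) {
  h <- object$history
  K <- object$design$skeleton$K
  is_tite <- object$design$method %in% c("TITE_CRM", "TITE_EWOC")
  w <- if (nrow(h)) {
    if (is_tite) tryCatch(history_effective(h, object$design$window)$w,
                          error = function(e) rep(NA_real_, nrow(h)))
    else rep(1, nrow(h))
  } else numeric(0)
  per_patient <- data.frame(
    id = h$id, dose_level = h$dose_level,
    outcome = ifelse(is.na(h$outcome), "pending", as.character(h$outcome)),
    followup = h$followup, weight = w)
  resolved_dlt <- !is.na(h$outcome) & h$outcome == 1L
  per_dose <- data.frame(
    level = seq_len(K),
    n_treated = as.integer(tabulate(h$dose_level, K)),
    n_dlt = as.integer(tabulate(h$dose_level[resolved_dlt], K)))
  per_dose$obs_rate <- ifelse(per_dose$n_treated > 0,
                              per_dose$n_dlt / per_dose$n_treated, NA_real_)
  est <- if (!is.null(object$next_recommendation))
    object$next_recommendation$estimates else NULL
  per_dose$estimate <- if (is.null(est)) NA_real_ else est
  trajectory <- data.frame(patient = h$id, level = h$dose_level)
  structure(list(per_patient = per_patient, per_dose = per_dose,
                 trajectory = trajectory, name = object$name,
                 status = object$status),
            class = "summary.crm_trial")
}

#' @export
print.summary.crm_trial <- function(x, ...) {
  cat(sprintf("Trial '%s' (%s)\n", x$name, x$status))
  cat("Per patient:\n"); print(x$per_patient, row.names = FALSE)
  cat("Per dose level:\n"); print(x$per_dose, row.names = FALSE)
  invisible(x)
}

#' Escalation trajectory plot
#'
#' @param x A \code{crm_trial}.
#' @param ... Passed to \code{plot}.
#' @export
plot.crm_trial <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("nothing to plot: empty trial")
  graphics::plot(h$id, h$dose_level, type = "s",
                 xlab = "patient", ylab = "dose level",
                 ylim = c(1, x$design$skeleton$K), yaxt = "n", ...)
  graphics::axis(2, at = seq_len(x$design$skeleton$K))
  dlt <- !is.na(h$outcome) & h$outcome == 1L
  graphics::points(h$id, h$dose_level,
                   pch = ifelse(dlt, 17, 1),
                   col = ifelse(dlt, "red3", "black"))
  invisible(x)
}

# ---- persistence ----------------------------------------------------------

design_to_list <- function(d) {
  list(method = d$method,
       skeleton = list(probs = d$skeleton$probs, theta = d$skeleton$theta,
                       nu = d$skeleton$nu, delta = d$skeleton$delta,
                       labels = d$skeleton$labels),
       model = list(family = d$model$family, intercept = d$model$intercept),
       prior = list(family = d$prior$family, parameters = d$prior$parameters),
       alpha = d$alpha, window = d$window, start_level = d$start_level,
       no_skip = d$no_skip, estimate = d$estimate,
       stopping = lapply(d$stopping, function(r)
         list(kind = r$kind, n = r$n, m = r$m, level = r$level)),
       run_in = d$run_in,
       ewoc_priors = if (is.null(d$ewoc_priors)) NULL else
         lapply(d$ewoc_priors, function(p)
           list(family = p$family, parameters = p$parameters)),
       nodes = d$nodes, ewoc_nodes = d$ewoc_nodes)
}

prior_from_list <- function(l) {
  do.call(prior_spec, c(list(family = l$family), l$parameters))
}

design_from_list <- function(l) {
  sk <- crm_skeleton(unlist(l$skeleton$probs), l$skeleton$theta,
                     l$skeleton$nu, delta = l$skeleton$delta,
                     labels = unlist(l$skeleton$labels))
  model <- if (is.null(l$model$intercept))
    dose_model(l$model$family) else
    dose_model(l$model$family, intercept = l$model$intercept)
  stopping <- lapply(l$stopping, function(r)
    stopping_rule(r$kind, n = r$n, m = r$m,
                  level = if (is.null(r$level)) "recommended" else r$level))
  ewoc_priors <- if (is.null(l$ewoc_priors)) NULL else
    lapply(l$ewoc_priors, prior_from_list)
  crm_design(l$method, sk, model = model, prior = prior_from_list(l$prior),
             alpha = l$alpha, window = l$window,
             start_level = l$start_level, no_skip = l$no_skip,
             estimate = l$estimate, stopping = stopping,
             run_in = l$run_in, ewoc_priors = ewoc_priors,
             nodes = l$nodes, ewoc_nodes = l$ewoc_nodes)
}

#' Persist and reload a trial
#'
#' The whole trial state (design, history, recommendations, status, audit
#' trail) is stored as a single structured JSON document carrying a
#' \code{schema_version}; loading a file written by a future schema is an
#' error. Writes are atomic (write-then-rename). A reloaded trial reproduces
#' the same recommendations as the original.
#'
#' @param trial A \code{crm_trial}.
#' @param path File path.
#' @return \code{save_trial} returns \code{path} invisibly;
#'   \code{load_trial} returns the \code{crm_trial}.
#' @export
save_trial <- function(trial, path) {
  stopifnot(inherits(trial, "crm_trial"))
  doc <- list(schema_version = trial$schema_version,
              name = trial$name,
              status = trial$status,
              design = design_to_list(trial$design),
              history = as.list(as.data.frame(trial$history)),
              recommendations = as.list(trial$recommendations),
              audit = trial$audit)
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_trial
#' @export
load_trial <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop("corrupted trial file: ",
                                           conditionMessage(e)))
  if (is.null(doc$schema_version))
    stop("corrupted trial file: missing schema_version")
  if (doc$schema_version > TRIAL_SCHEMA_VERSION)
    stop(sprintf("trial file has schema version %d; this build reads <= %d",
                 doc$schema_version, TRIAL_SCHEMA_VERSION))
  design <- design_from_list(doc$design)
  h <- doc$history
  history <- if (is.null(h) || !length(h$dose_level)) trial_history() else
    trial_history(h$dose_level, h$outcome, h$followup)
  recs <- doc$recommendations
  recs <- if (is.null(recs) || !length(recs$patient))
    data.frame(patient = integer(), recommended = integer(),
               administered = integer())
  else data.frame(patient = as.integer(recs$patient),
                  recommended = as.integer(recs$recommended),
                  administered = as.integer(recs$administered))
  trial <- structure(
    list(design = design, name = doc$name, history = history,
         recommendations = recs, status = doc$status,
         audit = doc$audit, schema_version = as.integer(doc$schema_version)),
    class = "crm_trial")
  if (trial$status != "stopped" || nrow(history)) {
    rec <- tryCatch(recommend_dose(design, history), error = function(e) e)
    if (inherits(rec, "error")) trial$pending_block <- conditionMessage(rec)
    else trial$next_recommendation <- rec
  }
  trial
}

#' Export trial summaries as delimited text
#'
#' Writes \code{per_patient.csv}, \code{per_dose.csv} and
#' \code{trajectory.csv} into a directory.
#'
#' @param trial A \code{crm_trial}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "crm_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summary(trial)
  paths <- file.path(dir, c("per_patient.csv", "per_dose.csv",
                            "trajectory.csv"))
  utils::write.csv(s$per_patient, paths[1L], row.names = FALSE)
  utils::write.csv(s$per_dose, paths[2L], row.names = FALSE)
  utils::write.csv(s$trajectory, paths[3L], row.names = FALSE)
  invisible(paths)
}
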