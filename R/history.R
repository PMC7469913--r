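#' Accumulating patient records of a dose-finding trial
#'
#' A trial history is the ordered table \eqn{\Omega_j} of patients treated so
#' far: the dose level given, the DLT outcome (1, 0, or pending), and the
#' follow-up time inside the observation window. Pending outcomes are stored
#' as \code{NA} and contribute through their time-to-event weight in TITE
#' designs.
#'
#' @param dose_level Integer dose-level indices.
#' @param outcome 0 (no DLT), 1 (DLT) or \code{NA} (pending). The strings
#'   \code{"pending"} and \code{"p"} are accepted and mapped to \code{NA}.
#' @param followup Follow-up time on study, in the units of the observation
#'   window; \code{NA} for non-TITE designs.
#' @return A data frame of class \code{crm_history} with columns \code{id},
#'   \code{dose_level}, \code{outcome}, \code{followup}.
#' @export
trial_history <- function(dose_level = integer(), outcome = integer(),
                          followup = NULL) {
  if (is.character(outcome))
    outcome <- ifelse(outcome %in% c("pending", "p"), NA, outcome)
  outcome <- suppressWarnings(as.integer(outcome))
  dose_level <- as.integer(dose_level)
  n <- length(dose_level)
  if (length(outcome) != n)
    stop("'dose_level' and 'outcome' must have the same length")
  if (is.null(followup)) followup <- rep(NA_real_, n)
  followup <- as.numeric(followup)
  if (length(followup) != n)
    stop("'followup' must match the number of records")
  if (any(!is.na(outcome) & !(outcome %in% 0:1)))
    stop("outcomes must be 0, 1 or pending (NA)")
  if (n && any(dose_level < 1L))
    stop("dose levels must be positive indices")
  h <- data.frame(id = seq_len(n), dose_level = dose_level,
                  outcome = outcome, followup = followup)
  class(h) <- c("crm_history", "data.frame")
  h
}

#' @export
print.crm_history <- function(x, ...) {
  cat(sprintf("Trial history: %d patient(s), %d DLT(s), %d pending\n",
              nrow(x), sum(x$outcome == 1L, na.rm = TRUE),
              sum(is.na(x$outcome))))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

append_record <- function(history, dose_level, outcome, followup = NA_real_) {
  r <- trial_history(dose_level, outcome, followup)
  r$id <- nrow(history) + 1L
  out <- rbind(as.data.frame(history), as.data.frame(r))
  class(out) <- c("crm_history", "data.frame")
  out
}

#' Linear time-to-event weight
#'
#' The TITE weight of a patient followed for time \code{u} out of an
#' observation window of length \code{window}: \eqn{u/T} while on follow-up
#' without DLT, and exactly 1 as soon as a DLT is observed.
#'
#' @param u Follow-up time(s), \code{0 <= u <= window}.
#' @param window Observation window length \eqn{T > 0}.
#' @param outcome 0/\code{NA} (no DLT so far) or 1 (DLT).
#' @return Weight(s) in [0, 1].
#' @examples
#' tite_weight(2, 4, 0)   # 0.5: two months of follow-up out of four
#' @export
tite_weight <- function(u, window, outcome = 0) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("'window' must be a single positive duration")
  n <- max(length(u), length(outcome))
  u <- rep_len(as.numeric(u), n)
  outcome <- rep_len(outcome, n)
  dlt <- !is.na(outcome) & outcome == 1
  if (any(!dlt & is.na(u)))
    stop("follow-up time required for patients without a DLT")
  uu <- ifelse(is.na(u), window, u)
  if (any(uu < 0) || any(uu > window))
    stop("follow-up must satisfy 0 <= u <= window")
  ifelse(dlt, 1, uu / window)
}

# Effective (y, w) pairs entering the weighted likelihood. Pending records
# enter as y = 0 with their partial weight; in non-TITE designs every weight
# is 1 and pending outcomes are not allowed at estimation time.
history_effective <- function(history, window = NULL) {
  n <- nrow(history)
  if (!n) return(list(y = numeric(0), w = numeric(0)))
  y <- ifelse(is.na(history$outcome), 0, history$outcome)
  if (is.null(window)) {
    if (anyNA(history$outcome))
      stop("pending outcomes require an observation window (TITE design); ",
           "non-TITE designs need every outcome resolved before estimation")
    w <- rep(1, n)
  } else {
    u <- history$followup
    # resolved outcomes with unrecorded follow-up count as fully observed
    u[is.na(u) & !is.na(history$outcome)] <- window
    w <- tite_weight(u, window, history$outcome)
    w[!is.na(history$outcome) & history$outcome == 0L &
        is.na(history$followup)] <- 1
  }
  list(y = as.numeric(y), w = as.numeric(w))
}

#' Read or write a trial history as delimited text
#'
#' Histories are exchanged as tab- or comma-separated tables with columns
#' \code{id}, \code{dose_level}, \code{outcome} (0/1/\code{pending}) and
#' \code{followup}.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return \code{read_history} returns a \code{\link{trial_history}};
#'   \code{write_history} returns \code{path} invisibly.
#' @export
read_history <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character")
  need <- c("dose_level", "outcome", "followup")
  if (!all(need %in% names(d)))
    stop("history file must have columns dose_level, outcome, followup")
  fu <- suppressWarnings(as.numeric(d$followup))
  trial_history(as.integer(d$dose_level), d$outcome, fu)
}

#' @rdname read_history
#' @param history A \code{\link{trial_history}}.
#' @export
write_history <- function(history, path, sep = "\t") {
  d <- as.data.frame(history)
  d$outcome <- ifelse(is.na(d$outcome), "pending", as.character(d$outcome))
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
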