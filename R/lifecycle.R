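#' Claim lifecycle states and transitions
#'
#' The billing life cycle runs request, authorization, claim, and then denial
#' or completion; a refused submission may be corrected or resubmitted and
#' reanalyzed by the payer. Statuses are the five-value code set
#' `tiss_status::submitted|pending|denied|returned_for_correction|completed`.
#' The transition relation is the minimal one consistent with that cycle:
#' COMPLETED is the unique terminal state, every state is reachable from
#' SUBMITTED, and DENIED / RETURNED_FOR_CORRECTION lead back to SUBMITTED.
#' Payer-specific overrides can be loaded from a JSON config file.
#'
#' @param state a claim status name.
#' @param relation a transition relation as returned by [transition_relation()].
#' @return `claim_statuses()`: the five status names; `allowed_transitions()`:
#'   character vector of permitted successor states (empty for COMPLETED);
#'   `transition_relation()`: named list state -> successors.
#' @examples
#' allowed_transitions("DENIED")
#' @export
claim_statuses <- function() {
  c("SUBMITTED", "PENDING", "DENIED", "RETURNED_FOR_CORRECTION", "COMPLETED")
}

#' @rdname claim_statuses
#' @export
transition_relation <- function() {
  list(
    SUBMITTED = c("PENDING", "DENIED", "RETURNED_FOR_CORRECTION", "COMPLETED"),
    PENDING = c("DENIED", "RETURNED_FOR_CORRECTION", "COMPLETED"),
    DENIED = "SUBMITTED",
    RETURNED_FOR_CORRECTION = "SUBMITTED",
    COMPLETED = character()
  )
}

assert_status <- function(state) {
  if (!is_string(state) || !(state %in% claim_statuses())) {
    stop_tiss(sprintf("unknown claim status: '%s'", paste(state, collapse = "")),
              "tiss_lifecycle_error")
  }
  state
}

#' @rdname claim_statuses
#' @export
allowed_transitions <- function(state, relation = transition_relation()) {
  assert_status(state)
  relation[[state]] %||% character()
}

#' @rdname claim_statuses
#' @param path file path for the transition-relation config (JSON object
#'   mapping each state to an array of successor states).
#' @export
write_transition_config <- function(relation = transition_relation(), path) {
  jsonlite::write_json(relation, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname claim_statuses
#' @export
read_transition_config <- function(path) {
  rel <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rel <- lapply(rel, function(x) as.character(unlist(x)))
  bad <- setdiff(c(names(rel), unlist(rel, use.names = FALSE)), claim_statuses())
  if (length(bad)) {
    stop_tiss(paste("unknown states in transition config:", paste(bad, collapse = ", ")),
              "tiss_lifecycle_error")
  }
  rel
}

#' Lifecycle transition records
#'
#' An `ism_transition` records that a submission entered a state at a given
#' time; a lifecycle history is an ordered list of them with non-decreasing
#' timestamps, starting in SUBMITTED.
#'
#' @param current_state one of [claim_statuses()].
#' @param timestamp ISO-8601 timestamp of the transition.
#' @param careflow_step optional careflow step label.
#' @return an `ism_transition` object.
#' @export
ism_transition <- function(current_state, timestamp, careflow_step = NULL) {
  structure(list(
    current_state = assert_status(current_state),
    careflow_step = if (is.null(careflow_step)) NULL else assert_string(careflow_step, "careflow_step"),
    timestamp = canonical_datetime(timestamp)
  ), class = "tiss_ism_transition")
}

#' @export
print.tiss_ism_transition <- function(x, ...) {
  cat(sprintf("<ISM_TRANSITION> %s @ %s\n", x$current_state, x$timestamp))
  invisible(x)
}

#' Extend a lifecycle history
#'
#' Appends a transition iff it is legal from the last recorded state and does
#' not regress in time; the input history is never mutated, a new one is
#' returned. An empty history may only be opened with SUBMITTED.
#'
#' @param history list of [ism_transition()] records.
#' @param next_state the state to enter.
#' @param at ISO-8601 timestamp of the transition.
#' @param relation transition relation to enforce.
#' @return the extended history.
#' @export
apply_transition <- function(history, next_state, at, relation = transition_relation()) {
  assert_status(next_state)
  at <- canonical_datetime(at)
  if (length(history) == 0L) {
    if (!identical(next_state, "SUBMITTED")) {
      stop_tiss(sprintf("a lifecycle must open with SUBMITTED, not %s", next_state),
                "tiss_lifecycle_error")
    }
    return(list(ism_transition(next_state, at)))
  }
  last <- history[[length(history)]]
  if (!(next_state %in% allowed_transitions(last$current_state, relation))) {
    stop_tiss(sprintf("illegal transition %s -> %s", last$current_state, next_state),
              "tiss_lifecycle_error", from = last$current_state, to = next_state)
  }
  if (at < last$timestamp) {
    stop_tiss(sprintf("time regression: %s precedes %s", at, last$timestamp),
              "tiss_lifecycle_error")
  }
  c(history, list(ism_transition(next_state, at)))
}

#' Validate a lifecycle history
#'
#' Checks that the history opens in SUBMITTED, that every consecutive pair of
#' states is in the transition relation, and that timestamps never decrease.
#' Problems are findings in a validation report, never exceptions.
#'
#' @inheritParams apply_transition
#' @return a [validation_report()].
#' @export
validate_history <- function(history, relation = transition_relation()) {
  findings <- list()
  add <- function(i, rule, detail) {
    findings[[length(findings) + 1L]] <<-
      validation_finding(sprintf("/lifecycle[%d]", i), rule, detail)
  }
  if (length(history) == 0L) return(validation_report(list()))
  if (!identical(history[[1L]]$current_state, "SUBMITTED")) {
    add(1L, "BAD_INITIAL_STATE",
        sprintf("history opens in %s, expected SUBMITTED", history[[1L]]$current_state))
  }
  if (length(history) > 1L) {
    for (i in 2:length(history)) {
      from <- history[[i - 1L]]
      to <- history[[i]]
      if (!(to$current_state %in% allowed_transitions(from$current_state, relation))) {
        add(i, "ILLEGAL_TRANSITION",
            sprintf("%s -> %s is not permitted", from$current_state, to$current_state))
      }
      if (to$timestamp < from$timestamp) {
        add(i, "TIME_REGRESSION",
            sprintf("%s precedes %s", to$timestamp, from$timestamp))
      }
    }
  }
  validation_report(findings)
}

# Status code set used in status elements of plain-RM claims.
status_to_text <- function(state) {
  tolower(gsub("_", " ", assert_status(state)))
}

status_from_text <- function(txt) {
  state <- toupper(gsub("[ -]+", "_", trimws(txt)))
  assert_status(state)
}
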