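#' Participant state for the decision engine
#'
#' Running state replayed from a participant's EMA log in chronological
#' order.  It carries exactly what the tailoring rules need: the study
#' phase, whether the participant smoked today or yesterday (set by
#' self-initiated smoking reports and shifted at day rollover), the
#' percent-chance-of-smoking rating from the first daily assessment, and
#' the participant's current interest in quitting.
#'
#' @param arm Treatment arm label.
#' @param cal A [study_calendar()].
#' @param quit_interest `"interested"` (default) or `"not_interested"`.
#' @return An object of class `participant_state`.
#' @export
participant_state <- function(arm = "smart_t2", cal = study_calendar(),
                              quit_interest = "interested") {
  structure(
    list(
      cal = cal,
      arm = arm,
      day = cal$baseline_day,
      last_time = -Inf,
      phase = study_phase(cal$baseline_day, cal),
      smoked_today = FALSE,
      smoked_yesterday = FALSE,
      first_daily_likelihood = NA_real_,
      quit_interest = quit_interest
    ),
    class = "participant_state"
  )
}

#' @export
print.participant_state <- function(x, ...) {
  cat("Participant state (day", x$day, ",", x$phase, "):",
      "smoked_today =", x$smoked_today,
      "| smoked_yesterday =", x$smoked_yesterday,
      "| first-daily likelihood =", x$first_daily_likelihood,
      "| quit interest:", x$quit_interest, "\n")
  invisible(x)
}

#' Apply one EMA response to the participant state
#'
#' Responses must arrive in chronological order.  Crossing a day boundary
#' shifts `smoked_today` into `smoked_yesterday` and clears the first-daily
#' likelihood; a `smoking_report` sets `smoked_today`; the first completed
#' assessment of a day that carries the likelihood item records it as the
#' day's `first_daily_likelihood` (later reports the same day are ignored).
#'
#' @param state A [participant_state()].
#' @param response One-row data.frame in the [ema_log] dialect.
#' @param day Integer day index of the response (defaults to the row's own
#'   `day`).
#' @return The updated `participant_state`.
#' @export
update_state <- function(state, response, day = response$day) {
  day <- as.integer(day)
  if (day < state$day ||
      (day == state$day && !is.na(response$time) && response$time < state$last_time))
    stop("update_state: responses out of chronological order (day ", day,
         " after day ", state$day, ")")
  while (state$day < day) {
    state$smoked_yesterday <- state$smoked_today
    state$smoked_today <- FALSE
    state$first_daily_likelihood <- NA_real_
    state$day <- state$day + 1L
  }
  state$phase <- study_phase(state$day, state$cal)
  state$last_time <- if (is.na(response$time)) state$last_time else response$time

  if (isTRUE(response$completed == 1L)) {
    if (response$initiation == "smoking_report") state$smoked_today <- TRUE
    if (is.na(state$first_daily_likelihood) && !is.na(response$likelihood))
      state$first_daily_likelihood <- response$likelihood
  }
  state
}

#' Replay an EMA log into per-response state snapshots
#'
#' Applies a single participant's responses in chronological order and
#' returns, for each row, the state *after* that response was absorbed --
#' which is the state the decision engine acts on at EMA completion.
#'
#' @param log Data.frame in the [ema_log] dialect for one participant,
#'   any row order (sorted internally by day then time).
#' @param cal A [study_calendar()].
#' @param interest Optional data.frame (`participant_id`, `day`) listing
#'   days on which the participant reported no longer being interested in
#'   quitting; all other days are `"interested"`.
#' @return The sorted log with appended columns `phase`, `smoked_today`,
#'   `smoked_yesterday`, `first_daily_likelihood`, `quit_interest`.
#' @export
replay_states <- function(log, cal = study_calendar(), interest = NULL) {
  stopifnot(length(unique(log$participant_id)) <= 1L)
  log <- log[order(log$day, log$time), , drop = FALSE]
  n <- nrow(log)
  st <- participant_state(arm = if (n) log$arm[1] else "smart_t2", cal = cal)
  off_days <- if (is.null(interest)) integer(0) else
    interest$day[interest$participant_id %in% log$participant_id]

  phase <- character(n); s_today <- logical(n); s_yday <- logical(n)
  lik <- numeric(n); qi <- character(n)
  for (i in seq_len(n)) {
    st <- update_state(st, log[i, , drop = FALSE])
    phase[i] <- st$phase
    s_today[i] <- st$smoked_today
    s_yday[i] <- st$smoked_yesterday
    lik[i] <- st$first_daily_likelihood
    qi[i] <- if (log$day[i] %in% off_days) "not_interested" else "interested"
  }
  log$phase <- phase
  log$smoked_today <- s_today
  log$smoked_yesterday <- s_yday
  log$first_daily_likelihood <- lik
  log$quit_interest <- qi
  log
}
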