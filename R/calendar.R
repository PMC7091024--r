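#' Study calendar for a 35-day EMA quit attempt
#'
#' Defines the day indexing used throughout the package.  Day 0 is the
#' baseline visit; the scheduled quit date falls exactly one week later; the
#' EMA observation window covers the 7 prequit days and the 28 postquit days
#' (35 consecutive days, days 0 to 34).  Follow-up assessment visits are
#' placed 4 and 12 weeks after the quit date.
#'
#' @param baseline_day Integer day index of the baseline visit (default 0).
#' @return An object of class `study_calendar` with fields `baseline_day`,
#'   `quit_day`, `ema_end_day` (first day *after* the EMA window) and
#'   `followup_days` (4-week and 12-week postquit visit days).
#' @examples
#' cal <- study_calendar()
#' cal$quit_day      # 7
#' ema_days(cal)     # 0..34
#' @export
study_calendar <- function(baseline_day = 0L) {
  baseline_day <- as.integer(baseline_day)
  cal <- structure(
    list(
      baseline_day  = baseline_day,
      quit_day      = baseline_day + 7L,
      ema_end_day   = baseline_day + 7L + 28L,
      followup_days = c(week4 = baseline_day + 7L + 28L,
                        week12 = baseline_day + 7L + 84L)
    ),
    class = "study_calendar"
  )
  validate_calendar(cal)
  cal
}

validate_calendar <- function(cal) {
  stopifnot(
    cal$quit_day == cal$baseline_day + 7L,
    cal$ema_end_day == cal$quit_day + 28L
  )
  invisible(cal)
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("Study calendar: baseline day", x$baseline_day,
      "| quit day", x$quit_day,
      "| EMA window", x$baseline_day, "-", x$ema_end_day - 1L,
      "(", x$ema_end_day - x$baseline_day, "days )\n")
  cat("Follow-up visit days:", paste(x$followup_days, collapse = ", "), "\n")
  invisible(x)
}

#' Days of the EMA observation window
#'
#' @param cal A [study_calendar()].
#' @return Integer vector of the 35 day indices carrying EMA prompts.
#' @export
ema_days <- function(cal) {
  seq.int(cal$baseline_day, cal$ema_end_day - 1L)
}

#' Study phase of a day
#'
#' Days strictly before the quit date are `"prequit"`, the quit date and
#' later are `"postquit"`.
#'
#' @param day Integer day index (vectorised).
#' @param cal A [study_calendar()].
#' @return Character vector, `"prequit"` or `"postquit"`.
#' @export
study_phase <- function(day, cal) {
  ifelse(day < cal$quit_day, "prequit", "postquit")
}

#' Build a seeded EMA prompt schedule
#'
#' Each of the 35 EMA days carries five prompts: one daily diary, placed at
#' the start of the waking window so that it is the first assessment of the
#' day, and four random assessments drawn uniformly from the waking window
#' subject to a minimum gap between any two same-day prompts (the diary
#' included).  The draw is fully determined by `seed`.
#'
#' @param cal A [study_calendar()].
#' @param participant_id Identifier stamped on every prompt.
#' @param window Numeric length-2 waking window, minutes from midnight
#'   (default 08:00-22:00).
#' @param min_gap Minimum spacing in minutes between same-day prompts
#'   (default 40).
#' @param seed Integer seed; required.
#' @return A data.frame with columns `participant_id`, `day`, `time`
#'   (minutes from midnight), `kind` (`"daily_diary"` or `"random"`),
#'   ordered by day then time; 5 rows per day, 175 rows in total for the
#'   default calendar.
#' @examples
#' s <- build_schedule(study_calendar(), "P1", seed = 42)
#' nrow(s)                       # 175
#' table(s$kind)                 # 35 diaries, 140 random
#' @export
build_schedule <- function(cal, participant_id = "P1",
                           window = c(8 * 60, 22 * 60),
                           min_gap = 40, seed) {
  if (missing(seed) || is.null(seed)) stop("build_schedule: a seed is required")
  if (length(window) != 2L || window[2] <= window[1])
    stop("build_schedule: 'window' must be increasing minutes-from-midnight")
  if (diff(window) < 5 * min_gap)
    stop("build_schedule: waking window too short for 5 prompts at min_gap = ",
         min_gap, " (needs >= ", 5 * min_gap, " minutes)")

  days <- ema_days(cal)
  out <- with_seed(as.integer(seed), {
    per_day <- lapply(days, function(d) {
      diary_time <- window[1]
      times <- draw_spaced_times(4L, lo = window[1], hi = window[2],
                                 min_gap = min_gap, anchor = diary_time)
      data.frame(
        participant_id = participant_id,
        day = d,
        time = c(diary_time, times),
        kind = c("daily_diary", rep("random", 4L)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_day)
  })
  rownames(out) <- NULL
  out
}

# Rejection-sample k times uniform on [lo, hi], all pairwise gaps >= min_gap,
# and each >= min_gap away from the fixed anchor time.
draw_spaced_times <- function(k, lo, hi, min_gap, anchor) {
  repeat {
    t <- sort(round(stats::runif(k, lo, hi)))
    all_t <- c(anchor, t)
    if (all(diff(sort(all_t)) >= min_gap)) return(t)
  }
}

# Evaluate expr under a local, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
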