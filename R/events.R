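#' Engagement-event logging
#'
#' App interactions outside the EMA stream -- on-demand quit tips and
#' medication tips, counselor calls, nicotine-replacement refill requests,
#' staff calls, payment-screen views, yes/no answers to the gum prompt, and
#' generic app opens/actions -- are recorded as append-only events.
#'
#' @name engagement_events
NULL

event_kinds <- c(
  "quit_tip_view", "medication_tip_view", "call_counselor", "order_nrt",
  "call_staff", "payment_view", "gum_yes", "gum_no", "app_open", "app_action"
)

#' Create an empty event log
#'
#' @return Zero-row data.frame with columns `participant_id`, `kind`,
#'   `subcategory`, `day`, `time`.
#' @export
event_log <- function() {
  data.frame(participant_id = character(0), kind = character(0),
             subcategory = character(0), day = integer(0),
             time = numeric(0), stringsAsFactors = FALSE)
}

#' Append an engagement event
#'
#' @param log Event log data.frame.
#' @param participant_id Identifier.
#' @param kind One of the recognised event kinds (see [engagement_events]).
#' @param subcategory Optional label (e.g. the tip category viewed).
#' @param day,time When the event occurred.
#' @return The extended log.
#' @export
record_event <- function(log, participant_id, kind, subcategory = NA,
                         day = NA, time = NA) {
  if (!kind %in% event_kinds)
    stop("unknown event kind '", kind, "'")
  rbind(log, data.frame(participant_id = participant_id, kind = kind,
                        subcategory = as.character(subcategory),
                        day = as.integer(day), time = as.numeric(time),
                        stringsAsFactors = FALSE))
}

#' Count events by kind (and optionally subcategory or day)
#'
#' @param log Event log data.frame.
#' @param by Character vector of grouping columns (default `"kind"`).
#' @return Data.frame of group combinations with an `n` count column; empty
#'   logs give a zero-row result.
#' @export
count_events <- function(log, by = "kind") {
  if (!nrow(log)) {
    out <- log[, by, drop = FALSE]
    out$n <- integer(0)
    return(out)
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(log))), by = log[by],
                          FUN = sum)
  agg[do.call(order, agg[by]), , drop = FALSE]
}

#' Fraction of gum prompts answered yes
#'
#' @param log Event log containing `gum_yes` / `gum_no` events.
#' @return Proportion of yes answers among answered gum prompts, or `NA`
#'   when none were answered.
#' @export
gum_yes_fraction <- function(log) {
  yes <- sum(log$kind == "gum_yes")
  no <- sum(log$kind == "gum_no")
  if (yes + no == 0) return(NA_real_)
  yes / (yes + no)
}

#' Read / write event logs as JSON lines
#'
#' @param log Event log data.frame.
#' @param path File path.
#' @return `read_events` returns the event data.frame; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    row <- as.list(log[i, , drop = FALSE])
    row$subcategory <- if (is.na(row$subcategory)) NULL else row$subcategory
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                dataframe = "rows"), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(event_log())
  recs <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    data.frame(participant_id = o$participant_id, kind = o$kind,
               subcategory = if (is.null(o$subcategory)) NA_character_
                             else o$subcategory,
               day = if (is.null(o$day)) NA_integer_ else as.integer(o$day),
               time = if (is.null(o$time)) NA_real_ else as.numeric(o$time),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
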