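#' Message banks
#'
#' Intervention content is organised into nine categories: `prequit_prep`
#' (preparing for the upcoming quit attempt), `low_risk` (abstinence
#' motivation and general cessation advice), the four trigger-tailored
#' high-risk categories (`high_risk_urge`, `high_risk_stress`,
#' `high_risk_availability`, `high_risk_motivation`), `lapse_recovery`
#' (treating a lapse as a learning experience, supporting a return to
#' abstinence), `daily_treatment` (day-level messages such as quit-date
#' reminders), and `gum_prompt` (the fixed nicotine-gum prompt shown at
#' high-risk moments).
#'
#' A bank is a data.frame with columns `id`, `category`, `text`; on disk it
#' is a JSON array of objects with those fields.
#'
#' @name message_bank
NULL

message_categories <- c(
  "prequit_prep", "low_risk", "high_risk_urge", "high_risk_stress",
  "high_risk_availability", "high_risk_motivation", "lapse_recovery",
  "daily_treatment", "gum_prompt"
)

gum_prompt_text <- paste(
  "Chewing a piece of nicotine gum right now may reduce your risk for",
  "smoking. Will you chew a piece of nicotine gum right now?"
)

#' Read a message bank from JSON
#'
#' @param path Path to a JSON array of `{id, category, text}` objects.
#' @return Validated bank data.frame.
#' @export
read_message_bank <- function(path) {
  bank <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  validate_message_bank(bank)
}

#' Validate a message bank
#'
#' Checks columns, known categories, unique ids, non-empty categories, and
#' that the gum-prompt category carries the fixed prompt text.
#'
#' @param bank Bank data.frame.
#' @return The bank, invisibly on success.
#' @export
validate_message_bank <- function(bank) {
  if (!all(c("id", "category", "text") %in% names(bank)))
    stop("message bank needs columns id, category, text")
  bad <- setdiff(unique(bank$category), message_categories)
  if (length(bad))
    stop("unknown message categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(bank$id))
    stop("duplicate message ids in bank")
  empty <- setdiff(message_categories, unique(bank$category))
  if (length(empty))
    stop("empty message categories: ", paste(empty, collapse = ", "))
  if (!gum_prompt_text %in% bank$text[bank$category == "gum_prompt"])
    stop("gum_prompt category must contain the canonical gum prompt text")
  invisible(bank)
}

#' The bundled stub message bank
#'
#' A minimal bank with placeholder content (at least three messages per
#' category) plus the canonical gum-prompt text; intended for testing and
#' simulation, not clinical use.
#'
#' @return Bank data.frame.
#' @export
default_message_bank <- function() {
  read_message_bank(system.file("extdata", "message_bank.json",
                                package = "jitair", mustWork = TRUE))
}

#' Tailored message decision at EMA completion
#'
#' Applies the engine's routing to one completed assessment:
#' prequit-phase responses draw from `prequit_prep`; postquit responses
#' from a participant who lapsed and is no longer interested in quitting
#' draw from `lapse_recovery`; otherwise low-risk responses draw from
#' `low_risk` and high-risk responses from the `high_risk_*` category of
#' the dominant trigger, accompanied by the nicotine-gum prompt.  Within a
#' category the least-recently-delivered message is chosen (bank order
#' breaks ties).
#'
#' @param state A [participant_state()] current as of the response (i.e.
#'   with the response already absorbed).
#' @param response One-row data.frame in the [ema_log] dialect.
#' @param bank Message bank data.frame.
#' @param history Character vector of previously delivered message ids for
#'   this participant, oldest first.
#' @param config A [risk_config()].
#' @return A list of class `jitai_decision`: `risk_score`, `risk_class`,
#'   `trigger` (or `NA`), `message` (one bank row), `gum_prompt` (logical).
#' @export
deliver_message <- function(state, response, bank,
                            history = character(0),
                            config = risk_config()) {
  validate_message_bank(bank)
  score <- compute_risk_score(response, config)
  class <- classify_risk(state, response, config)
  trigger <- NA_character_
  gum <- FALSE
  lapsed <- isTRUE(state$smoked_today) || isTRUE(state$smoked_yesterday)

  if (state$phase == "prequit") {
    category <- "prequit_prep"
  } else if (identical(state$quit_interest, "not_interested") && lapsed) {
    category <- "lapse_recovery"
  } else if (class == "high" &&
             identical(state$quit_interest, "interested")) {
    trigger <- select_trigger(response, config$trigger_priority)
    category <- paste0("high_risk_", trigger)
    gum <- TRUE
  } else {
    category <- "low_risk"
  }

  msg <- pick_least_recent(bank, category, history)
  structure(
    list(risk_score = score, risk_class = class, trigger = trigger,
         message = msg, gum_prompt = gum),
    class = "jitai_decision"
  )
}

# Least-recently-used message within a category; unseen messages first in
# bank order.
pick_least_recent <- function(bank, category, history) {
  rows <- bank[bank$category == category, , drop = FALSE]
  if (!nrow(rows)) stop("message bank has no messages in category ", category)
  last_seen <- vapply(rows$id, function(id) {
    hits <- which(history == id)
    if (length(hits)) max(hits) else 0L
  }, integer(1))
  rows[which.min(last_seen), , drop = FALSE]
}

#' @export
print.jitai_decision <- function(x, ...) {
  cat(sprintf("Decision: score %.3f (%s)%s%s -> [%s] %s\n",
              x$risk_score, x$risk_class,
              if (!is.na(x$trigger)) paste0(", trigger ", x$trigger) else "",
              if (x$gum_prompt) ", gum prompt" else "",
              x$message$id, x$message$category))
  invisible(x)
}

#' Run the decision engine over an EMA log
#'
#' Replays each participant's responses chronologically and emits exactly
#' one decision per completed assessment; missed prompts yield none.
#'
#' @param log Data.frame in the [ema_log] dialect (any number of
#'   participants).
#' @param bank Message bank data.frame.
#' @param config A [risk_config()].
#' @param cal A [study_calendar()].
#' @param interest Optional not-interested day table, see [replay_states()].
#' @return Decision log data.frame: `participant_id`, `day`, `time`,
#'   `response_key`, `risk_score`, `risk_class`, `trigger`, `message_id`,
#'   `category`, `gum_prompt`.
#' @export
decide <- function(log, bank = default_message_bank(),
                   config = risk_config(), cal = study_calendar(),
                   interest = NULL) {
  validate_message_bank(bank)
  out <- lapply(split(log, log$participant_id), function(plog) {
    rep_log <- replay_states(plog, cal, interest)
    done <- rep_log[rep_log$completed == 1L, , drop = FALSE]
    if (!nrow(done)) return(NULL)
    history <- character(0)
    recs <- vector("list", nrow(done))
    for (i in seq_len(nrow(done))) {
      row <- done[i, , drop = FALSE]
      st <- list(phase = row$phase, smoked_today = row$smoked_today,
                 smoked_yesterday = row$smoked_yesterday,
                 first_daily_likelihood = row$first_daily_likelihood,
                 quit_interest = row$quit_interest)
      d <- deliver_message(st, row, bank, history, config)
      history <- c(history, d$message$id)
      recs[[i]] <- data.frame(
        participant_id = row$participant_id, day = row$day, time = row$time,
        # sequence index keeps keys unique even if a self-initiated report
        # lands on the same minute as a prompt
        response_key = paste(row$participant_id, row$day, row$time, i,
                             sep = ":"),
        risk_score = d$risk_score, risk_class = d$risk_class,
        trigger = d$trigger, message_id = d$message$id,
        category = d$message$category, gum_prompt = d$gum_prompt,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read / write decision logs as JSON lines
#'
#' One JSON object per decision; scores serialised at 6 decimal places.
#'
#' @param decisions Decision log from [decide()].
#' @param path File path.
#' @return `read_decisions` returns the decision data.frame;
#'   `write_decisions` returns `path` invisibly.
#' @export
write_decisions <- function(decisions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(decisions))) {
    row <- decisions[i, , drop = FALSE]
    obj <- list(
      response_key = row$response_key,
      participant_id = row$participant_id,
      day = row$day, time = row$time,
      risk_score = sprintf("%.6f", row$risk_score),
      risk_class = row$risk_class,
      trigger = if (is.na(row$trigger)) NULL else row$trigger,
      message_id = row$message_id, category = row$category,
      gum_prompt = isTRUE(row$gum_prompt)
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    data.frame(
      participant_id = o$participant_id, day = o$day, time = o$time,
      response_key = o$response_key,
      risk_score = as.numeric(o$risk_score), risk_class = o$risk_class,
      trigger = if (is.null(o$trigger)) NA_character_ else o$trigger,
      message_id = o$message_id, category = o$category,
      gum_prompt = o$gum_prompt, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
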