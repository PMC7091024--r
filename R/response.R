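#' @name ema_log
#' @title The EMA log dialect
#'
#' @description
#' EMA responses travel as long-format data.frames, one row per prompted or
#' self-initiated assessment, with exactly these columns:
#'
#' * `participant_id` -- identifier
#' * `arm` -- `"smart_t2"`, `"quitguide"` or `"usual_care"`
#' * `day` -- integer day index, 0-based from baseline
#' * `time` -- minutes from midnight
#' * `kind` -- `"random"` or `"daily_diary"` for scheduled prompts, `NA` for
#'   self-initiated reports
#' * `initiation` -- `"prompted"`, `"urge_report"` or `"smoking_report"`
#' * `urge`, `stress`, `availability` -- Likert 1 (not at all) to 5
#' * `motivation` -- Likert 1 to 5, *reverse-coded*: 1 = strongly agree that
#'   the participant is motivated to avoid smoking, so higher values mean
#'   lower motivation and higher lapse risk
#' * `with_smoker`, `alcohol` -- 0/1 binary exposures
#' * `likelihood` -- self-rated percent chance (0-100) of smoking before the
#'   end of the day; present only on the first daily assessment
#' * `gum_pieces`, `patch_category`, `drinks` -- daily-diary extras (pieces of
#'   nicotine gum 0-8+, patch wear-time category label, drinks 0-8+); present
#'   iff `kind == "daily_diary"`
#' * `completed` -- 0/1; scheduled prompts that went unanswered keep their row
#'   with `completed = 0` and empty item fields
#'
#' On disk the log is plain CSV with empty strings for missing fields; see
#' [read_ema_log()] / [write_ema_log()].
NULL

ema_log_columns <- c(
  "participant_id", "arm", "day", "time", "kind", "initiation",
  "urge", "stress", "availability", "motivation", "with_smoker", "alcohol",
  "likelihood", "gum_pieces", "patch_category", "drinks", "completed"
)

likert_items <- c("urge", "stress", "availability", "motivation")
diary_extras <- c("gum_pieces", "patch_category", "drinks")

#' Construct a single EMA response row
#'
#' Convenience constructor used by the simulator and in tests; returns a
#' one-row data.frame in the [ema_log] dialect.
#'
#' @param participant_id,arm,day,time,kind,initiation Identification fields.
#' @param urge,stress,availability,motivation Likert 1-5 item values
#'   (`motivation` reverse-coded: higher = less motivated).
#' @param with_smoker,alcohol Binary exposures (0/1).
#' @param likelihood Percent 0-100, or `NA` when the item was not shown.
#' @param gum_pieces,patch_category,drinks Daily-diary extras.
#' @param completed 0/1 completion flag.
#' @return One-row data.frame with the [ema_log] columns.
#' @export
ema_response <- function(participant_id = "P1", arm = "smart_t2",
                         day = 0L, time = 480, kind = "random",
                         initiation = "prompted",
                         urge = NA, stress = NA, availability = NA,
                         motivation = NA, with_smoker = NA, alcohol = NA,
                         likelihood = NA, gum_pieces = NA,
                         patch_category = NA, drinks = NA, completed = 1L) {
  data.frame(
    participant_id = participant_id, arm = arm, day = as.integer(day),
    time = as.numeric(time), kind = as.character(kind),
    initiation = as.character(initiation),
    urge = as.numeric(urge), stress = as.numeric(stress),
    availability = as.numeric(availability),
    motivation = as.numeric(motivation),
    with_smoker = as.numeric(with_smoker), alcohol = as.numeric(alcohol),
    likelihood = as.numeric(likelihood),
    gum_pieces = as.numeric(gum_pieces),
    patch_category = as.character(patch_category),
    drinks = as.numeric(drinks),
    completed = as.integer(completed),
    stringsAsFactors = FALSE
  )
}

#' Validate one EMA response
#'
#' Checks the range and presence invariants of the [ema_log] dialect: Likert
#' items in 1..5, binary exposures in \{0, 1\}, likelihood in \[0, 100\],
#' a known `initiation` value, and daily-diary extras present only on daily
#' diaries.  Items may be missing (an incomplete response); what is present
#' must be in range.
#'
#' @param response One-row data.frame (or coercible list) in the [ema_log]
#'   dialect.
#' @return The validated response, invisibly.  On failure an error is thrown
#'   whose message names the offending field.
#' @export
validate_response <- function(response) {
  r <- as.data.frame(response, stringsAsFactors = FALSE)
  if (nrow(r) != 1L) stop("validate_response expects a single response row")
  reason <- response_violation(r)
  if (!is.na(reason)) stop("invalid EMA response: ", reason)
  invisible(r)
}

# First violated invariant of a 1-row response, or NA if clean.
response_violation <- function(r) {
  for (item in likert_items) {
    v <- r[[item]]
    if (!is.na(v) && (v %% 1 != 0 || v < 1 || v > 5))
      return(paste0(item, ": Likert value ", v, " outside 1..5"))
  }
  for (item in c("with_smoker", "alcohol")) {
    v <- r[[item]]
    if (!is.na(v) && !v %in% c(0, 1))
      return(paste0(item, ": binary value ", v, " not 0/1"))
  }
  if (!is.na(r$likelihood) && (r$likelihood < 0 || r$likelihood > 100))
    return(paste0("likelihood: ", r$likelihood, " outside [0,100]"))
  if (!r$initiation %in% c("prompted", "urge_report", "smoking_report"))
    return(paste0("initiation: unknown value '", r$initiation, "'"))
  if (!is.na(r$kind) && !r$kind %in% c("random", "daily_diary"))
    return(paste0("kind: unknown value '", r$kind, "'"))
  is_diary <- !is.na(r$kind) && r$kind == "daily_diary"
  if (!is_diary) {
    for (item in diary_extras) {
      if (!is.na(r[[item]]))
        return(paste0(item, ": daily-diary item present on a non-diary response"))
    }
  }
  NA_character_
}

#' Validate an EMA log, splitting accepted from rejected rows
#'
#' @param log Data.frame in the [ema_log] dialect.
#' @return List with `accepted` (clean rows) and `rejected` (offending rows
#'   plus a `reason` column naming the violated field).
#' @export
validate_ema_log <- function(log) {
  log <- check_ema_columns(log)
  reasons <- vapply(seq_len(nrow(log)),
                    function(i) response_violation(log[i, , drop = FALSE]),
                    character(1))
  rejected <- log[!is.na(reasons), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!is.na(reasons)]
  list(accepted = log[is.na(reasons), , drop = FALSE], rejected = rejected)
}

check_ema_columns <- function(log) {
  missing <- setdiff(ema_log_columns, names(log))
  if (length(missing))
    stop("EMA log is missing columns: ", paste(missing, collapse = ", "))
  log[, ema_log_columns, drop = FALSE]
}

#' Read / write EMA logs as CSV
#'
#' Plain-text CSV in the [ema_log] dialect; missing fields are empty strings
#' on disk and `NA` in memory.
#'
#' @param path File path.
#' @param log Data.frame in the [ema_log] dialect.
#' @return `read_ema_log` returns the log data.frame; `write_ema_log`
#'   returns `path` invisibly.
#' @export
read_ema_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character",
                                        arm = "character",
                                        kind = "character",
                                        initiation = "character",
                                        patch_category = "character"))
  log$kind[!is.na(log$kind) & log$kind == ""] <- NA_character_
  pc <- log$patch_category
  log$patch_category[!is.na(pc) & pc == ""] <- NA_character_
  check_ema_columns(log)
}

#' @rdname read_ema_log
#' @export
write_ema_log <- function(log, path) {
  log <- check_ema_columns(log)
  utils::write.csv(format_for_csv(log), path, row.names = FALSE, na = "")
  invisible(path)
}

# Fixed 6-decimal formatting for floating-point columns so reruns are
# byte-stable.
format_for_csv <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- df[[nm]]
      whole <- !is.na(v) & v %% 1 == 0
      out <- character(length(v))
      out[whole] <- formatC(v[whole], format = "d")
      out[!whole & !is.na(v)] <- formatC(v[!whole & !is.na(v)],
                                         format = "f", digits = 6)
      out[is.na(v)] <- NA_character_
      df[[nm]] <- out
    }
  }
  df
}

#' Serialize a prompt schedule as CSV
#'
#' Same dialect as the EMA log without item columns.
#'
#' @param schedule Data.frame from [build_schedule()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE, na = "")
  invisible(path)
}
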