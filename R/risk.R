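#' Configuration of the weighted lapse-risk formula
#'
#' The momentary lapse-risk score is a weighted sum of six EMA-reported
#' factors: urge to smoke, stress, recent alcohol use, interaction with
#' someone smoking, (low) motivation to quit, and cigarette availability.
#' The weights that discriminate high- from low-risk moments were estimated
#' in prior lapse-prediction work and are *not* published alongside the
#' engine; they are required configuration.  The defaults below are an
#' illustrative, non-canonical weighting used for documentation and testing
#' only -- any deployment must supply its own estimated weights.
#'
#' @param weights Named nonnegative numeric vector with entries `urge`,
#'   `stress`, `alcohol`, `interaction`, `motivation`, `availability`.
#'   Normalised to sum to 1.
#' @param risk_threshold Score threshold tau in \[0, 1\] at or above which a
#'   response is classified high risk (default 0.5, illustrative).
#' @param likelihood_threshold Percent threshold for the first-daily
#'   "chance I smoke today" rule; ratings *strictly above* it flag the day
#'   high risk (default 25).
#' @param likelihood_scope `"day"` (default): the over-threshold flag holds
#'   for the rest of the calendar day; `"report_only"`: it applies only to
#'   the assessment that carried the rating.
#' @param trigger_priority Tie-break order for [select_trigger()].
#' @return An object of class `risk_config`.
#' @export
risk_config <- function(weights = c(urge = 0.25, stress = 0.15,
                                    alcohol = 0.05, interaction = 0.15,
                                    motivation = 0.15, availability = 0.25),
                        risk_threshold = 0.5,
                        likelihood_threshold = 25,
                        likelihood_scope = c("day", "report_only"),
                        trigger_priority = c("urge", "availability",
                                             "stress", "motivation")) {
  need <- c("urge", "stress", "alcohol", "interaction", "motivation",
            "availability")
  if (!all(need %in% names(weights)))
    stop("risk_config: weights must name all of: ", paste(need, collapse = ", "))
  weights <- weights[need]
  if (any(weights < 0)) {
    bad <- need[weights < 0][1]
    stop("risk_config: negative weight for '", bad, "'")
  }
  if (sum(weights) <= 0) stop("risk_config: weights sum to zero")
  weights <- weights / sum(weights)
  if (risk_threshold < 0 || risk_threshold > 1)
    stop("risk_config: risk_threshold must lie in [0,1]")
  if (likelihood_threshold < 0 || likelihood_threshold > 100)
    stop("risk_config: likelihood_threshold must lie in [0,100]")
  likelihood_scope <- match.arg(likelihood_scope)
  triggers <- c("urge", "stress", "availability", "motivation")
  if (!setequal(trigger_priority, triggers))
    stop("risk_config: trigger_priority must order exactly: ",
         paste(triggers, collapse = ", "))
  structure(
    list(weights = weights,
         risk_threshold = risk_threshold,
         likelihood_threshold = likelihood_threshold,
         likelihood_scope = likelihood_scope,
         trigger_priority = trigger_priority),
    class = "risk_config"
  )
}

#' @export
print.risk_config <- function(x, ...) {
  cat("Lapse-risk configuration\n  weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = " "),
      "\n  risk threshold:", x$risk_threshold,
      "| likelihood threshold: >", x$likelihood_threshold,
      "% (", x$likelihood_scope, ")\n  trigger priority:",
      paste(x$trigger_priority, collapse = " > "), "\n")
  invisible(x)
}

#' Momentary lapse-risk score
#'
#' Weighted sum of the six risk factors, each rescaled to \[0, 1\]: Likert
#' items map value v to (v - 1)/4 -- the motivation item is already
#' reverse-coded on its 1-5 scale, so its raw value enters directly (higher
#' = less motivated = riskier) -- and the two binary exposures map to
#' \{0, 1\}.  With normalised weights the score lies in \[0, 1\] and is
#' monotone nondecreasing in every factor.
#'
#' Vectorised over the rows of `response`.
#'
#' @param response Data.frame in the [ema_log] dialect (any number of rows).
#' @param config A [risk_config()].
#' @return Numeric vector of scores in \[0, 1\]; `NA` where any factor is
#'   missing.
#' @examples
#' r <- ema_response(urge = 5, stress = 3, availability = 4, motivation = 2,
#'                   with_smoker = 1, alcohol = 0)
#' compute_risk_score(r, risk_config())   # 0.70
#' @export
compute_risk_score <- function(response, config = risk_config()) {
  w <- config$weights
  rescale <- function(v) (v - 1) / 4
  w[["urge"]]         * rescale(response$urge) +
  w[["stress"]]       * rescale(response$stress) +
  w[["alcohol"]]      * response$alcohol +
  w[["interaction"]]  * response$with_smoker +
  w[["motivation"]]   * rescale(response$motivation) +
  w[["availability"]] * rescale(response$availability)
}

#' Classify a response as low or high lapse risk
#'
#' A completed assessment is high risk when *any* of these hold:
#' the risk score reaches the threshold (`score >= tau`); the participant
#' already smoked that day or the day before; or the participant rated
#' their chance of smoking today strictly above the likelihood threshold
#' on the first daily assessment.  Otherwise it is low risk.
#'
#' Vectorised over rows: `state` fields and `response` rows may be vectors
#' of matching length.
#'
#' @param state A [participant_state()], current as of the response, or a
#'   list with fields `smoked_today`, `smoked_yesterday`,
#'   `first_daily_likelihood`.
#' @param response Data.frame in the [ema_log] dialect.
#' @param config A [risk_config()].
#' @return Character vector, `"high"` or `"low"` per row.
#' @export
classify_risk <- function(state, response, config = risk_config()) {
  score <- compute_risk_score(response, config)
  lik <- state$first_daily_likelihood
  if (config$likelihood_scope == "report_only") lik <- response$likelihood
  smoked_today <- as.logical(state$smoked_today)
  smoked_today[is.na(smoked_today)] <- FALSE
  smoked_yesterday <- as.logical(state$smoked_yesterday)
  smoked_yesterday[is.na(smoked_yesterday)] <- FALSE
  high <- (!is.na(score) & score >= config$risk_threshold) |
    smoked_today | smoked_yesterday |
    (!is.na(lik) & lik > config$likelihood_threshold)
  ifelse(high, "high", "low")
}

#' Select the dominant lapse trigger for message tailoring
#'
#' High-risk messages are tailored to whichever of the four momentary
#' triggers -- urge to smoke, stress, easy cigarette availability, low
#' motivation to quit -- currently carries the highest rating.  The
#' motivation item is reverse-coded on entry, so all four ratings are
#' directly comparable; ties go to the earliest trigger in the configured
#' priority order.
#'
#' @param response One-row data.frame in the [ema_log] dialect.
#' @param priority Character vector ordering the four triggers.
#' @return One of `"urge"`, `"stress"`, `"availability"`, `"motivation"`.
#' @export
select_trigger <- function(response,
                           priority = risk_config()$trigger_priority) {
  ratings <- c(urge = response$urge, stress = response$stress,
               availability = response$availability,
               motivation = response$motivation)
  ratings <- ratings[priority]
  names(ratings)[which.max(ratings)]
}
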