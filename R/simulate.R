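#' Simulator configuration
#'
#' Parameters of the synthetic three-arm cohort generator.  The generator
#' emulates the data-generating structure the engine and analyses assume:
#' per-participant prompt-answering compliance drawn from a Beta
#' distribution; 1-5 Likert items drawn from item-specific discretised
#' latent normals; binary exposures as Bernoulli draws; a first-daily
#' percent likelihood tied to the momentary risk score; a lapse process in
#' which each answered postquit assessment triggers a lapse with
#' probability `plogis(lapse_intercept + lapse_slope * risk_score)`;
#' geometric dropout; and carbon-monoxide readings at visits whose mean
#' depends on smoking status.
#'
#' @param n_per_arm Participants per arm (default 27, a 3 x 27 = 81 cohort).
#' @param compliance_alpha,compliance_beta Beta shape parameters for the
#'   per-participant probability of answering a scheduled prompt (default
#'   Beta(8.4, 1.6), mean 0.84).
#' @param likert_mu,likert_sigma Named latent means / SDs for `urge`,
#'   `stress`, `availability`, `motivation`.
#' @param p_with_smoker,p_alcohol Bernoulli rates of the binary exposures.
#' @param likelihood_sd SD (percent points) of the first-daily likelihood
#'   rating around its risk-linked mean.
#' @param lapse_intercept,lapse_slope Logistic coefficients linking the
#'   risk score of an answered postquit assessment to lapse probability.
#' @param p_prequit_report Daily rate of self-initiated smoking reports
#'   during the prequit week (participants are still smoking).
#' @param p_urge_report Daily rate of self-initiated urge reports.
#' @param p_lose_interest Probability that a lapse day is reported with no
#'   remaining interest in quitting (drives lapse-recovery routing).
#' @param dropout_hazard Per-day probability of withdrawal.
#' @param persist_abstinent Probability that week-4 abstinence carries
#'   through to week 12.
#' @param p_late_quit Probability that a week-4 smoker is abstinent at
#'   week 12.
#' @param p_false_claim Probability that a smoking participant self-reports
#'   no puff at a visit (caught by the CO check).
#' @param co_abstinent_mean,co_smoking_mean,co_noise_sd Expired-CO model
#'   (ppm): status-dependent mean plus Gaussian noise, truncated at 0.
#' @param p_gum_yes Probability a delivered gum prompt is answered yes.
#' @param risk A [risk_config()] used to score simulated responses.
#' @param seed Integer seed; required.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 27L,
                       compliance_alpha = 8.4, compliance_beta = 1.6,
                       likert_mu = c(urge = 2.8, stress = 2.5,
                                     availability = 3.2, motivation = 2.0),
                       likert_sigma = c(urge = 1.2, stress = 1.2,
                                        availability = 1.3, motivation = 1.0),
                       p_with_smoker = 0.2, p_alcohol = 0.1,
                       likelihood_sd = 15,
                       lapse_intercept = -4, lapse_slope = 3,
                       p_prequit_report = 0.5, p_urge_report = 0.1,
                       p_lose_interest = 0.2,
                       dropout_hazard = 0.0044,
                       persist_abstinent = 0.75, p_late_quit = 0.05,
                       p_false_claim = 0.1,
                       co_abstinent_mean = 3, co_smoking_mean = 15,
                       co_noise_sd = 1.5,
                       p_gum_yes = 0.65,
                       risk = risk_config(),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: a seed is required")
  stopifnot(
    n_per_arm >= 1, compliance_alpha > 0, compliance_beta > 0,
    all(c("urge", "stress", "availability", "motivation") %in%
          names(likert_mu)),
    all(likert_sigma > 0),
    p_with_smoker >= 0, p_with_smoker <= 1, p_alcohol >= 0, p_alcohol <= 1,
    likelihood_sd >= 0, dropout_hazard >= 0, dropout_hazard <= 1,
    persist_abstinent >= 0, persist_abstinent <= 1,
    p_false_claim >= 0, p_false_claim <= 1, co_noise_sd >= 0,
    p_gum_yes >= 0, p_gum_yes <= 1
  )
  structure(
    list(n_per_arm = as.integer(n_per_arm),
         compliance_alpha = compliance_alpha,
         compliance_beta = compliance_beta,
         likert_mu = likert_mu, likert_sigma = likert_sigma,
         p_with_smoker = p_with_smoker, p_alcohol = p_alcohol,
         likelihood_sd = likelihood_sd,
         lapse_intercept = lapse_intercept, lapse_slope = lapse_slope,
         p_prequit_report = p_prequit_report, p_urge_report = p_urge_report,
         p_lose_interest = p_lose_interest,
         dropout_hazard = dropout_hazard,
         persist_abstinent = persist_abstinent, p_late_quit = p_late_quit,
         p_false_claim = p_false_claim,
         co_abstinent_mean = co_abstinent_mean,
         co_smoking_mean = co_smoking_mean, co_noise_sd = co_noise_sd,
         p_gum_yes = p_gum_yes, risk = risk, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Per-participant RNG substream seed derived from the global seed; kept
# inside 32-bit integer range.
participant_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 1000003 * idx) %% 2147483647)
}

draw_likert <- function(n, mu, sigma) {
  pmin(pmax(round(stats::rnorm(n, mu, sigma)), 1), 5)
}

# Minutes after the triggering assessment at which a simulated lapse is
# self-reported; fixed so (assessment, lapse) pairs are recoverable from
# the log.
lapse_report_offset <- 5

#' Simulate one participant
#'
#' Draws the participant's compliance, walks their 35-day prompt schedule
#' answering items, generates self-initiated urge and smoking reports (the
#' postquit lapse process reports a lapse `lapse_report_offset` minutes
#' after the triggering assessment), applies dropout, and produces the
#' three outcome visits with CO readings.
#'
#' @param config A [sim_config()].
#' @param arm Arm label.
#' @param participant_id Identifier.
#' @param idx Participant index used to derive the RNG substream.
#' @param cal A [study_calendar()].
#' @return List with `ema`, `visits`, `interest` and `events` data.frames.
#' @export
simulate_participant <- function(config, arm, participant_id, idx,
                                 cal = study_calendar()) {
  pseed <- participant_seed(config$seed, idx)
  schedule <- build_schedule(cal, participant_id, seed = pseed)
  with_seed(participant_seed(config$seed, idx + 500000), {
    p_answer <- stats::rbeta(1, config$compliance_alpha,
                             config$compliance_beta)
    dropout_day <- if (config$dropout_hazard > 0)
      stats::rgeom(1, config$dropout_hazard) else Inf

    schedule <- schedule[schedule$day < dropout_day, , drop = FALSE]
    n <- nrow(schedule)
    answered <- stats::runif(n) < p_answer

    rows <- vector("list", 0L)
    lapse_days <- integer(0)
    interest_days <- integer(0)
    seen_day <- -1L
    for (i in seq_len(n)) {
      d <- schedule$day[i]
      t <- schedule$time[i]
      if (!answered[i]) {
        rows[[length(rows) + 1L]] <- ema_response(
          participant_id, arm, d, t, schedule$kind[i], "prompted",
          completed = 0L)
        next
      }
      is_diary <- schedule$kind[i] == "daily_diary"
      r <- ema_response(
        participant_id, arm, d, t, schedule$kind[i], "prompted",
        urge = draw_likert(1, config$likert_mu[["urge"]],
                           config$likert_sigma[["urge"]]),
        stress = draw_likert(1, config$likert_mu[["stress"]],
                             config$likert_sigma[["stress"]]),
        availability = draw_likert(1, config$likert_mu[["availability"]],
                                   config$likert_sigma[["availability"]]),
        motivation = draw_likert(1, config$likert_mu[["motivation"]],
                                 config$likert_sigma[["motivation"]]),
        with_smoker = stats::rbinom(1, 1, config$p_with_smoker),
        alcohol = stats::rbinom(1, 1, config$p_alcohol),
        completed = 1L)
      score <- compute_risk_score(r, config$risk)
      if (d > seen_day) {
        # first answered assessment of the day carries the likelihood item
        mu_lik <- 100 * stats::plogis(config$lapse_intercept +
                                        config$lapse_slope * score)
        r$likelihood <- round(pmin(pmax(
          stats::rnorm(1, mu_lik, config$likelihood_sd), 0), 100))
        seen_day <- d
      }
      if (is_diary) {
        r$gum_pieces <- stats::rbinom(1, 8, 0.6)
        r$patch_category <- sample(patch_categories(), 1,
                                   prob = c(1, 1, 1, 1, 2, 3, 4, 5, 6))
        r$drinks <- stats::rbinom(1, 8, 0.1)
      }
      rows[[length(rows) + 1L]] <- r
      # postquit lapse process, linked to this assessment's score
      if (d >= cal$quit_day &&
          stats::runif(1) < stats::plogis(config$lapse_intercept +
                                            config$lapse_slope * score)) {
        rows[[length(rows) + 1L]] <- simulate_report(
          config, participant_id, arm, d, t + lapse_report_offset,
          "smoking_report")
        lapse_days <- c(lapse_days, d)
        if (stats::runif(1) < config$p_lose_interest)
          interest_days <- c(interest_days, d)
      }
    }

    # self-initiated reports not tied to prompts
    for (d in ema_days(cal)) {
      if (d >= dropout_day) break
      if (d < cal$quit_day &&
          stats::runif(1) < config$p_prequit_report)
        rows[[length(rows) + 1L]] <- simulate_report(
          config, participant_id, arm, d,
          round(stats::runif(1, 8 * 60, 22 * 60)), "smoking_report")
      if (stats::runif(1) < config$p_urge_report)
        rows[[length(rows) + 1L]] <- simulate_report(
          config, participant_id, arm, d,
          round(stats::runif(1, 8 * 60, 22 * 60)), "urge_report")
    }

    ema <- if (length(rows)) do.call(rbind, rows) else ema_response()[0, ]
    ema <- ema[order(ema$day, ema$time), , drop = FALSE]
    rownames(ema) <- NULL

    visits <- simulate_visits(config, participant_id, arm, cal,
                              lapse_days, dropout_day)
    interest <- if (length(interest_days))
      data.frame(participant_id = participant_id,
                 day = sort(unique(interest_days)),
                 stringsAsFactors = FALSE)
    else data.frame(participant_id = character(0), day = integer(0))

    events <- simulate_app_events(config, participant_id, cal, dropout_day)

    list(ema = ema, visits = visits, interest = interest, events = events,
         dropout_day = dropout_day)
  })
}

simulate_report <- function(config, participant_id, arm, day, time, kind) {
  ema_response(
    participant_id, arm, day, time, NA, kind,
    urge = draw_likert(1, config$likert_mu[["urge"]],
                       config$likert_sigma[["urge"]]),
    stress = draw_likert(1, config$likert_mu[["stress"]],
                         config$likert_sigma[["stress"]]),
    availability = draw_likert(1, config$likert_mu[["availability"]],
                               config$likert_sigma[["availability"]]),
    motivation = draw_likert(1, config$likert_mu[["motivation"]],
                             config$likert_sigma[["motivation"]]),
    with_smoker = stats::rbinom(1, 1, config$p_with_smoker),
    alcohol = stats::rbinom(1, 1, config$p_alcohol),
    completed = 1L)
}

simulate_visits <- function(config, participant_id, arm, cal,
                            lapse_days, dropout_day) {
  quit_day <- cal$quit_day
  wk4 <- cal$followup_days[["week4"]]
  wk12 <- cal$followup_days[["week12"]]

  abst_quit <- !any(lapse_days == quit_day)
  abst_wk4 <- !any(lapse_days >= wk4 - 7 & lapse_days < wk4)
  abst_wk12 <- if (abst_wk4) stats::runif(1) < config$persist_abstinent
               else stats::runif(1) < config$p_late_quit

  mk <- function(visit, day, abst) {
    attended <- day < dropout_day
    if (!attended)
      return(data.frame(participant_id = participant_id, arm = arm,
                        visit = visit, day = day, attended = 0L,
                        self_report_no_puff = NA, co_ppm = NA_real_,
                        stringsAsFactors = FALSE))
    claim <- abst || stats::runif(1) < config$p_false_claim
    co_mu <- if (abst) config$co_abstinent_mean else config$co_smoking_mean
    co <- max(0, stats::rnorm(1, co_mu, config$co_noise_sd))
    data.frame(participant_id = participant_id, arm = arm, visit = visit,
               day = day, attended = 1L,
               self_report_no_puff = as.integer(claim),
               co_ppm = round(co, 1), stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(participant_id = participant_id, arm = arm,
               visit = "baseline", day = cal$baseline_day, attended = 1L,
               self_report_no_puff = NA, co_ppm = NA_real_,
               stringsAsFactors = FALSE),
    mk("quit_date", quit_day, abst_quit),
    mk("week4", wk4, abst_wk4),
    mk("week12", wk12, abst_wk12)
  )
}

simulate_app_events <- function(config, participant_id, cal, dropout_day) {
  log <- event_log()
  for (d in ema_days(cal)) {
    if (d >= dropout_day) break
    if (stats::runif(1) < 0.4)
      log <- record_event(log, participant_id, "app_open", day = d,
                          time = round(stats::runif(1, 8 * 60, 22 * 60)))
    if (stats::runif(1) < 0.1)
      log <- record_event(log, participant_id, "quit_tip_view",
                          subcategory = sample(c("general_advice",
                                                 "coping_others_smoking",
                                                 "harms_of_smoking",
                                                 "coping_mood"), 1),
                          day = d, time = round(stats::runif(1, 8 * 60, 22 * 60)))
    if (stats::runif(1) < 0.05)
      log <- record_event(log, participant_id, "medication_tip_view",
                          subcategory = "nicotine_gum", day = d,
                          time = round(stats::runif(1, 8 * 60, 22 * 60)))
    if (stats::runif(1) < 0.02)
      log <- record_event(log, participant_id, "order_nrt", day = d,
                          time = round(stats::runif(1, 8 * 60, 22 * 60)))
    if (stats::runif(1) < 0.02)
      log <- record_event(log, participant_id, "call_counselor", day = d,
                          time = round(stats::runif(1, 8 * 60, 22 * 60)))
  }
  log
}

#' Simulate a three-arm trial
#'
#' Independent participants, `n_per_arm` per arm, each generated by
#' [simulate_participant()] from its own seeded RNG substream -- identical
#' configurations (including the seed) reproduce the dataset exactly.
#'
#' @param config A [sim_config()].
#' @param arms Arm labels (default the three trial arms).
#' @param cal A [study_calendar()].
#' @return An object of class `trial_dataset`: list with `ema`, `visits`,
#'   `interest`, `events` data.frames plus the `config`, `cal` and a
#'   participant roster.
#' @export
simulate_trial <- function(config,
                           arms = c("smart_t2", "quitguide", "usual_care"),
                           cal = study_calendar()) {
  prefix <- c(smart_t2 = "T", quitguide = "G", usual_care = "U")
  idx <- 0L
  parts <- list()
  for (arm in arms) {
    for (i in seq_len(config$n_per_arm)) {
      idx <- idx + 1L
      pid <- sprintf("%s%03d", if (arm %in% names(prefix)) prefix[[arm]]
                               else toupper(substr(arm, 1, 1)), i)
      parts[[idx]] <- c(simulate_participant(config, arm, pid, idx, cal),
                        list(participant_id = pid, arm = arm))
    }
  }
  dataset <- structure(
    list(
      ema = do.call(rbind, lapply(parts, `[[`, "ema")),
      visits = do.call(rbind, lapply(parts, `[[`, "visits")),
      interest = do.call(rbind, lapply(parts, `[[`, "interest")),
      events = do.call(rbind, lapply(parts, `[[`, "events")),
      roster = data.frame(
        participant_id = vapply(parts, `[[`, character(1), "participant_id"),
        arm = vapply(parts, `[[`, character(1), "arm"),
        dropout_day = vapply(parts, function(p)
          as.numeric(p$dropout_day), numeric(1)),
        stringsAsFactors = FALSE),
      config = config, cal = cal),
    class = "trial_dataset"
  )
  rownames(dataset$ema) <- rownames(dataset$visits) <- NULL
  dataset
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Synthetic trial dataset:", nrow(x$roster), "participants in",
      length(unique(x$roster$arm)), "arms;",
      nrow(x$ema), "EMA rows;", nrow(x$visits), "visit rows\n")
  invisible(x)
}

#' Write a trial dataset to a directory
#'
#' Emits `ema.csv`, `visits.csv`, `interest.csv`, `events.jsonl` and a
#' `provenance.json` echoing the full configuration and seed.
#'
#' @param dataset A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ema_log(dataset$ema, file.path(dir, "ema.csv"))
  utils::write.csv(format_for_csv(dataset$visits),
                   file.path(dir, "visits.csv"), row.names = FALSE, na = "")
  utils::write.csv(dataset$interest, file.path(dir, "interest.csv"),
                   row.names = FALSE, na = "")
  write_events(dataset$events, file.path(dir, "events.jsonl"))
  prov <- dataset$config
  class(prov) <- NULL
  prov$risk <- unclass(prov$risk)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Extract (risk score, lapse) pairs from a simulated EMA log
#'
#' Pairs every completed prompted postquit assessment with an indicator of
#' whether a lapse was reported `lapse_report_offset` minutes after it --
#' the simulator's lapse bookkeeping -- so the logistic lapse model can be
#' refitted from the serialised log alone.
#'
#' @param ema EMA log in the [ema_log] dialect.
#' @param risk A [risk_config()] used to score assessments.
#' @param cal A [study_calendar()].
#' @return Data.frame with columns `score` and `lapse` (0/1).
#' @export
lapse_pairs <- function(ema, risk = risk_config(), cal = study_calendar()) {
  done <- ema[ema$completed == 1L & ema$initiation == "prompted" &
                ema$day >= cal$quit_day, , drop = FALSE]
  reports <- ema[ema$initiation == "smoking_report", , drop = FALSE]
  key <- paste(reports$participant_id, reports$day, reports$time)
  lapse <- paste(done$participant_id, done$day,
                 done$time + lapse_report_offset) %in% key
  data.frame(score = compute_risk_score(done, risk),
             lapse = as.integer(lapse))
}

#' Pooled prompted-EMA completion rate
#'
#' Completed prompted assessments over scheduled prompted assessments
#' (self-initiated reports excluded from both counts; prompts after a
#' participant's withdrawal are not in the log and hence not in the
#' denominator).
#'
#' @param ema EMA log in the [ema_log] dialect.
#' @return Fraction in \[0, 1\].
#' @export
completion_rate <- function(ema) {
  prompted <- ema[ema$initiation == "prompted", , drop = FALSE]
  if (!nrow(prompted)) return(NA_real_)
  mean(prompted$completed == 1L)
}
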