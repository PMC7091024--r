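# Shared fixtures built in code.

# A two-message-per-category toy bank for LRU tests; keeps the canonical
# gum prompt so validation passes.
toy_bank <- function(k = 2) {
  rows <- lapply(jitair:::message_categories, function(cat) {
    data.frame(id = sprintf("%s-%d", cat, seq_len(k)),
               category = cat,
               text = sprintf("%s stub %d", cat, seq_len(k)),
               stringsAsFactors = FALSE)
  })
  bank <- do.call(rbind, rows)
  bank$text[bank$id == "gum_prompt-1"] <- jitair:::gum_prompt_text
  bank
}

# Minimal completed response with every factor at its lowest-risk value.
minimal_response <- function(...) {
  args <- utils::modifyList(
    list(urge = 1, stress = 1, availability = 1, motivation = 1,
         with_smoker = 0, alcohol = 0),
    list(...))
  do.call(ema_response, args)
}

# Quiet state list for classify_risk / deliver_message.
quiet_state <- function(phase = "postquit", smoked_today = FALSE,
                        smoked_yesterday = FALSE,
                        first_daily_likelihood = NA_real_,
                        quit_interest = "interested") {
  list(phase = phase, smoked_today = smoked_today,
       smoked_yesterday = smoked_yesterday,
       first_daily_likelihood = first_daily_likelihood,
       quit_interest = quit_interest)
}

# Visit records with a given number of confirmed-abstinent participants
# per arm (the rest smoking, CO 20 ppm).
make_visits <- function(abst_by_arm, n = 27, visit = "week12") {
  rows <- list()
  for (arm in names(abst_by_arm)) {
    for (i in seq_len(n)) {
      abst <- i <= abst_by_arm[[arm]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = paste0(arm, i), arm = arm, visit = visit,
        self_report_no_puff = as.integer(abst),
        co_ppm = if (abst) 3 else 20, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Independent, literal transcription of the published high-risk rule, kept
# separate from the engine: high risk when the weighted score reaches the
# threshold, OR the participant smoked today or yesterday, OR the
# first-daily likelihood rating was strictly above the threshold.
oracle_classify <- function(urge, stress, availability, motivation,
                            with_smoker, alcohol, smoked_today,
                            smoked_yesterday, likelihood, weights, tau,
                            lik_threshold = 25) {
  score <- weights[["urge"]] * (urge - 1) / 4 +
    weights[["stress"]] * (stress - 1) / 4 +
    weights[["alcohol"]] * alcohol +
    weights[["interaction"]] * with_smoker +
    weights[["motivation"]] * (motivation - 1) / 4 +
    weights[["availability"]] * (availability - 1) / 4
  if (score >= tau) return("high")
  if (smoked_today) return("high")
  if (smoked_yesterday) return("high")
  if (!is.na(likelihood) && likelihood > lik_threshold) return("high")
  "low"
}

# Brute-force trigger oracle: scan triggers in priority order keeping the
# first strict maximum.
oracle_trigger <- function(ratings, priority) {
  best <- priority[1]
  for (tr in priority) if (ratings[[tr]] > ratings[[best]]) best <- tr
  best
}
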