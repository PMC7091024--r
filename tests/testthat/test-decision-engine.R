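test_that("risk score hits its extremes and the hand-computed example", {
  cfg <- risk_config()
  lo <- minimal_response()
  hi <- ema_response(urge = 5, stress = 5, availability = 5, motivation = 5,
                     with_smoker = 1, alcohol = 1)
  expect_equal(compute_risk_score(lo, cfg), 0)
  expect_equal(compute_risk_score(hi, cfg), 1)
  # hand-computed weighted sum:
  # .25*1 + .15*.5 + .05*0 + .15*1 + .15*.25 + .25*.75 = 0.70
  ex <- ema_response(urge = 5, stress = 3, availability = 4, motivation = 2,
                     with_smoker = 1, alcohol = 0)
  expect_equal(compute_risk_score(ex, cfg), 0.70)
})

test_that("risk configuration validates weights and thresholds", {
  expect_error(risk_config(weights = c(urge = -0.1, stress = .2,
                                       alcohol = .1, interaction = .2,
                                       motivation = .2, availability = .4)),
               "negative weight for 'urge'")
  expect_error(risk_config(risk_threshold = 1.2), "risk_threshold")
  expect_error(risk_config(likelihood_threshold = 101), "likelihood")
  # weights normalise to sum 1: doubling all weights changes nothing
  w <- c(urge = .5, stress = .3, alcohol = .1, interaction = .3,
         motivation = .3, availability = .5)
  r <- ema_response(urge = 4, stress = 2, availability = 3, motivation = 3,
                    with_smoker = 0, alcohol = 1)
  expect_equal(compute_risk_score(r, risk_config(weights = w)),
               compute_risk_score(r, risk_config(weights = 2 * w)))
})

test_that("high-risk classification follows the quoted disjunction", {
  cfg <- risk_config()
  base <- minimal_response()
  expect_equal(classify_risk(quiet_state(), base, cfg), "low")
  expect_equal(classify_risk(quiet_state(smoked_yesterday = TRUE),
                             base, cfg), "high")
  expect_equal(classify_risk(quiet_state(smoked_today = TRUE), base, cfg),
               "high")
  # strictly-greater-than rule on the 25% likelihood
  expect_equal(classify_risk(quiet_state(first_daily_likelihood = 25),
                             base, cfg), "low")
  expect_equal(classify_risk(quiet_state(first_daily_likelihood = 25.1),
                             base, cfg), "high")
})

test_that("classification matches a brute-force transcription over the factor grid", {
  grid <- expand.grid(urge = 1:5, stress = c(1, 5), availability = c(1, 5),
                      motivation = 1:5, with_smoker = 0:1, alcohol = 0:1,
                      smoked_today = c(FALSE, TRUE),
                      smoked_yesterday = c(FALSE, TRUE),
                      likelihood = c(NA, 0, 12.5, 25, 37.5, 100))
  responses <- ema_response(urge = grid$urge, stress = grid$stress,
                            availability = grid$availability,
                            motivation = grid$motivation,
                            with_smoker = grid$with_smoker,
                            alcohol = grid$alcohol)
  states <- list(smoked_today = grid$smoked_today,
                 smoked_yesterday = grid$smoked_yesterday,
                 first_daily_likelihood = grid$likelihood)
  set.seed(202)
  for (rep in 1:10) {
    w <- stats::runif(6)
    names(w) <- c("urge", "stress", "alcohol", "interaction", "motivation",
                  "availability")
    tau <- stats::runif(1)
    cfg <- risk_config(weights = w, risk_threshold = tau)
    got <- classify_risk(states, responses, cfg)
    want <- mapply(oracle_classify, grid$urge, grid$stress,
                   grid$availability, grid$motivation, grid$with_smoker,
                   grid$alcohol, grid$smoked_today, grid$smoked_yesterday,
                   grid$likelihood,
                   MoreArgs = list(weights = cfg$weights, tau = tau))
    expect_identical(got, unname(want))
  }
})

test_that("risk score and class are monotone in every factor", {
  cfg <- risk_config()
  set.seed(7)
  likerts <- c("urge", "stress", "availability", "motivation")
  bins <- c("with_smoker", "alcohol")
  for (i in 1:200) {
    vals <- c(as.list(sample(1:5, 4, replace = TRUE)),
              as.list(sample(0:1, 2, replace = TRUE)))
    names(vals) <- c(likerts, bins)
    r <- do.call(ema_response, vals)
    s <- compute_risk_score(r, cfg)
    cls <- classify_risk(quiet_state(), r, cfg)
    for (f in c(likerts, bins)) {
      top <- if (f %in% likerts) 5 else 1
      if (vals[[f]] == top) next
      bumped <- vals
      bumped[[f]] <- bumped[[f]] + 1
      r2 <- do.call(ema_response, bumped)
      s2 <- compute_risk_score(r2, cfg)
      expect_gte(s2, s)
      if (cls == "high")
        expect_equal(classify_risk(quiet_state(), r2, cfg), "high")
    }
  }
})

test_that("trigger selection is the priority-broken argmax over all 625 combinations", {
  priority <- risk_config()$trigger_priority
  grid <- expand.grid(urge = 1:5, stress = 1:5, availability = 1:5,
                      motivation = 1:5)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- ema_response(urge = g$urge, stress = g$stress,
                      availability = g$availability,
                      motivation = g$motivation,
                      with_smoker = 0, alcohol = 0)
    expect_identical(select_trigger(r, priority),
                     oracle_trigger(as.list(g), priority))
  }
  # highest-rated trigger wins; full tie goes to the priority head
  r <- ema_response(urge = 3, stress = 2, availability = 5, motivation = 1,
                    with_smoker = 0, alcohol = 0)
  expect_equal(select_trigger(r), "availability")
  tie <- ema_response(urge = 4, stress = 4, availability = 4,
                      motivation = 4, with_smoker = 0, alcohol = 0)
  expect_equal(select_trigger(tie), priority[1])
})

test_that("message routing follows phase, interest and risk", {
  bank <- toy_bank()
  cfg <- risk_config()
  hot <- ema_response(urge = 3, stress = 2, availability = 5,
                      motivation = 2, with_smoker = 1, alcohol = 0)

  d <- deliver_message(quiet_state(phase = "prequit"), hot, bank,
                       config = cfg)
  expect_equal(d$message$category, "prequit_prep")
  expect_false(d$gum_prompt)

  d <- deliver_message(quiet_state(), minimal_response(), bank, config = cfg)
  expect_equal(d$message$category, "low_risk")
  expect_false(d$gum_prompt)
  expect_true(is.na(d$trigger))

  d <- deliver_message(quiet_state(), hot, bank, config = cfg)
  expect_equal(d$risk_class, "high")
  expect_equal(d$trigger, "availability")
  expect_equal(d$message$category, "high_risk_availability")
  expect_true(d$gum_prompt)

  d <- deliver_message(quiet_state(smoked_today = TRUE,
                                   quit_interest = "not_interested"),
                       minimal_response(), bank, config = cfg)
  expect_equal(d$message$category, "lapse_recovery")
  expect_false(d$gum_prompt)

  empty <- bank[bank$category != "low_risk", ]
  expect_error(deliver_message(quiet_state(), minimal_response(), empty,
                               config = cfg),
               "low_risk")
})

test_that("within a category messages rotate least-recently-used", {
  bank <- toy_bank(k = 2)
  history <- character(0)
  seen <- character(0)
  for (i in 1:3) {
    d <- deliver_message(quiet_state(phase = "prequit"), minimal_response(),
                         bank, history, risk_config())
    seen <- c(seen, d$message$id)
    history <- c(history, d$message$id)
  }
  expect_equal(seen, c("prequit_prep-1", "prequit_prep-2", "prequit_prep-1"))
})

test_that("decide emits exactly one decision per completed assessment", {
  cfg <- sim_config(n_per_arm = 2, seed = 5)
  d <- simulate_trial(cfg, arms = "smart_t2")
  dec <- decide(d$ema, interest = d$interest)
  expect_equal(nrow(dec), sum(d$ema$completed == 1L))
  expect_equal(dec$response_key,
               unique(dec$response_key))
  # gum implication: gum prompts only on high-risk postquit decisions
  gum <- dec[dec$gum_prompt, ]
  expect_true(all(gum$risk_class == "high"))
  expect_true(all(gum$day >= study_calendar()$quit_day))
  # trigger present iff a trigger-tailored category was delivered
  expect_identical(!is.na(dec$trigger),
                   grepl("^high_risk_", dec$category))
})

test_that("decision logs round-trip through JSON lines with 6-decimal scores", {
  cfg <- sim_config(n_per_arm = 1, seed = 9)
  d <- simulate_trial(cfg, arms = "smart_t2")
  dec <- decide(d$ema, interest = d$interest)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_decisions(dec, path)
  back <- read_decisions(path)
  expect_equal(back$message_id, dec$message_id)
  expect_equal(back$risk_score, round(dec$risk_score, 6))
  expect_equal(back$trigger, dec$trigger)
})

test_that("event logs count by kind and support the gum yes-fraction", {
  log <- event_log()
  for (i in 1:3) log <- record_event(log, "P1", "quit_tip_view", day = i)
  log <- record_event(log, "P1", "gum_yes", day = 1)
  log <- record_event(log, "P1", "gum_yes", day = 2)
  log <- record_event(log, "P1", "gum_no", day = 3)
  counts <- count_events(log)
  expect_equal(counts$n[counts$kind == "quit_tip_view"], 3)
  expect_equal(gum_yes_fraction(log), 2 / 3)
  expect_error(record_event(log, "P1", "mystery"), "unknown event kind")
  expect_equal(nrow(count_events(event_log())), 0)
  expect_true(is.na(gum_yes_fraction(event_log())))
})
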