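test_that("abstinence needs a confirming self-report AND a CO reading under the cutoff", {
  expect_true(classify_abstinent(list(visit = "week12",
                                      self_report_no_puff = 1, co_ppm = 5)))
  expect_false(classify_abstinent(list(visit = "week12",
                                       self_report_no_puff = 1, co_ppm = 6)))
  expect_false(classify_abstinent(list(visit = "week12",
                                       self_report_no_puff = 0, co_ppm = 2)))
  # quit-date visit uses the 10 ppm washout cutoff
  expect_true(classify_abstinent(list(visit = "quit_date",
                                      self_report_no_puff = 1, co_ppm = 9)))
  expect_false(classify_abstinent(list(visit = "quit_date",
                                       self_report_no_puff = 1, co_ppm = 10)))
  # missing anything counts as smoking (intent to treat)
  expect_false(classify_abstinent(list(visit = "week12",
                                       self_report_no_puff = NA,
                                       co_ppm = 3)))
  expect_false(classify_abstinent(list(visit = "week12",
                                       self_report_no_puff = 1,
                                       co_ppm = NA)))
})

test_that("abstinence tables pool printed-style arm counts correctly", {
  v12 <- make_visits(c(smart_t2 = 6, quitguide = 4, usual_care = 4))
  t12 <- abstinence_table(v12, "week12")
  expect_equal(sort(t12$by_arm$abstinent), c(4, 4, 6))
  expect_equal(t12$pooled_abstinent, 14)
  expect_equal(t12$pooled_total, 81)
  expect_equal(t12$pooled_percent, 17)

  v4 <- make_visits(c(smart_t2 = 6, quitguide = 7, usual_care = 8),
                    visit = "week4")
  t4 <- abstinence_table(v4, "week4")
  expect_equal(t4$pooled_abstinent, 21)
  expect_equal(t4$pooled_percent, 26)

  all_abst <- make_visits(c(a = 5, b = 5), n = 5)
  expect_equal(abstinence_table(all_abst, "week12")$pooled_percent, 100)

  # a rostered participant with no visit row counts as smoking
  roster <- data.frame(participant_id = c(v12$participant_id, "extra"),
                       arm = c(v12$arm, "smart_t2"))
  t_itt <- abstinence_table(v12, "week12", roster)
  expect_equal(t_itt$pooled_total, 82)
  expect_equal(t_itt$pooled_abstinent, 14)
})

test_that("raising a CO cutoff never decreases the abstinent count", {
  set.seed(42)
  co <- round(stats::runif(60, 0, 20), 1)
  claims <- stats::rbinom(60, 1, 0.7)
  count_at <- function(cut) sum(claims == 1 & co < cut)
  cuts <- seq(2, 20, by = 2)
  counts <- vapply(cuts, count_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("Pearson chi-square matches the textbook formula on small tables", {
  oracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  week12 <- rbind(c(6, 21), c(4, 23), c(4, 23))
  res <- chisq_independence(week12)
  expect_equal(res$statistic, oracle(week12), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_gt(res$p_value, 0.05)

  # equal proportions give exactly zero
  flat <- rbind(c(5, 20), c(5, 20), c(5, 20))
  expect_equal(chisq_independence(flat)$statistic, 0)

  # sampled sweep of small 2x2 and 3x2 integer tables
  set.seed(11)
  for (i in 1:200) {
    r <- sample(2:3, 1)
    tab <- matrix(sample(1:30, r * 2, replace = TRUE), nrow = r)
    res <- chisq_independence(tab)
    expect_equal(res$statistic, oracle(tab), tolerance = 1e-9)
    expect_equal(res$df, (r - 1))
    expect_equal(res$p_value,
                 stats::pchisq(res$statistic, r - 1, lower.tail = FALSE))
  }
  expect_error(chisq_independence(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("summary ANOVA equals raw-data ANOVA and reproduces published-style rows", {
  rely <- data.frame(n = c(21, 22, 22), mean = c(4.33, 3.59, 3.95),
                     sd = c(0.66, 1.14, 0.95))
  res <- anova_from_summary(rely)
  expect_equal(res$F, 3.34, tolerance = 0.15 / 3.34)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 62)
  expect_lt(res$p_value, 0.05)

  flat <- data.frame(n = c(10, 10), mean = c(2, 2), sd = c(1, 2))
  expect_equal(anova_from_summary(flat)$F, 0)

  # property: summaries computed from raw data reproduce aov() exactly
  set.seed(9)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    n <- sample(3:12, k, replace = TRUE)
    y <- stats::rnorm(sum(n), mean = rep(stats::runif(k, 0, 5), n))
    grp <- factor(rep(seq_len(k), n))
    summ <- data.frame(
      n = as.integer(table(grp)),
      mean = tapply(y, grp, mean),
      sd = tapply(y, grp, sd))
    mine <- anova_from_summary(summ)
    ref <- stats::anova(stats::lm(y ~ grp))
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
  expect_error(anova_from_summary(data.frame(n = 5, mean = 1, sd = 1)),
               "two groups")
  expect_error(anova_from_summary(data.frame(n = c(5, 5), mean = c(1, 2),
                                             sd = c(0, 0))),
               "zero within-group")
})

test_that("compensation sums visit payments and the completion-tier bonus", {
  all_visits <- c("baseline", "quit_date", "week4", "week12")
  expect_equal(compensation(158, 175, all_visits), 290)  # 90.3% -> 150
  expect_equal(compensation(87, 175, all_visits), 140)   # 49.7% -> no bonus
  expect_equal(compensation(88, 175, all_visits), 190)   # 50.3% -> 50
  # inclusive lower boundary at exactly 50.0%
  expect_equal(compensation(50, 100, all_visits), 190)
  expect_equal(compensation(75, 100, all_visits), 240)
  expect_equal(compensation(90, 100, all_visits), 290)
  # missed visits forfeit their payments
  expect_equal(compensation(90, 100, c("baseline", "quit_date")), 210)
  expect_equal(compensation(0, 175, character(0)), 0)
  expect_error(compensation(180, 175, all_visits), "exceeds")
  expect_error(compensation(-1, 175, all_visits), "negative")
})

test_that("compensation is nondecreasing in completed prompts", {
  usd <- vapply(0:175, compensation, numeric(1), scheduled_prompted = 175,
                visits_attended = c("baseline", "quit_date", "week4",
                                    "week12"))
  expect_true(all(diff(usd) >= 0))
})

test_that("patch wear-time categories recode to band midpoints", {
  expect_equal(recode_patch_hours("I did not wear it at all"), 0)
  expect_equal(recode_patch_hours("Less than 3 hours"), 2)
  expect_equal(recode_patch_hours("4-6 hours"), 5)
  expect_equal(recode_patch_hours(c("19-21 hours", "At least 22-24 hours")),
               c(20, 23))
  expect_equal(length(patch_categories()), 9)
  expect_error(recode_patch_hours("sometimes"), "unknown category")
})

test_that("message distributions report high-risk shares and per-participant means", {
  counts <- c(high_risk_availability = 869, high_risk_urge = 630,
              high_risk_motivation = 85, high_risk_stress = 54)
  dec <- data.frame(
    participant_id = rep("T001", sum(counts)),
    day = 7L, time = 480,
    category = rep(names(counts), counts),
    gum_prompt = TRUE, stringsAsFactors = FALSE)
  md <- message_distribution(dec, n_participants = 27)
  expect_equal(sum(md$high_risk_shares), 100)
  expect_equal(round(md$high_risk_shares[["availability"]], 2), 53.05)
  expect_equal(round(md$high_risk_shares[["urge"]], 2), 38.46)
  expect_equal(round(md$high_risk_shares[["motivation"]], 2), 5.19)
  expect_equal(round(md$high_risk_shares[["stress"]], 2), 3.30)

  gum <- data.frame(participant_id = "x", day = 7L, time = 1,
                    category = "gum", gum_prompt = TRUE)
  md2 <- message_distribution(gum[rep(1, 861), ], n_participants = 27)
  expect_equal(round(md2$gum_per_participant, 1), 31.9)

  md0 <- message_distribution(data.frame(participant_id = character(0),
                                         day = integer(0), time = numeric(0),
                                         category = character(0),
                                         gum_prompt = logical(0)))
  expect_equal(md0$total_messages, 0)
  expect_null(md0$high_risk_shares)
})
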