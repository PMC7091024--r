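#' Carbon-monoxide verified abstinence classification
#'
#' Intent-to-treat 7-day point-prevalence abstinence: a participant counts
#' as abstinent at a visit only when they self-reported no smoking ("not
#' even a puff") over the reference period *and* their expired CO reading
#' fell strictly below 6 ppm -- 10 ppm at the quit-date visit, where recent
#' smoking is still washing out.  A missed visit, missing self-report or
#' missing CO reading counts as smoking.
#'
#' @param visit One-row data.frame (or list) with fields `visit`
#'   (`"quit_date"`, `"week4"` or `"week12"`), `self_report_no_puff`
#'   (0/1/`NA`) and `co_ppm` (ppm or `NA`).
#' @return Logical: `TRUE` if biochemically confirmed abstinent.
#' @export
classify_abstinent <- function(visit) {
  cutoff <- if (identical(visit$visit, "quit_date")) 10 else 6
  isTRUE(visit$self_report_no_puff == 1) &&
    !is.na(visit$co_ppm) && visit$co_ppm < cutoff
}

#' Per-arm abstinence table at a visit
#'
#' Classifies every rostered participant (intent-to-treat: those without a
#' usable visit record count as smoking) and tabulates abstinent / total
#' by arm, with the pooled percentage rounded half-up to an integer as
#' abstinence rates are conventionally reported.
#'
#' @param visits Visits data.frame (`participant_id`, `arm`, `visit`,
#'   `self_report_no_puff`, `co_ppm`).
#' @param visit Which visit to tabulate.
#' @param roster Optional data.frame (`participant_id`, `arm`) defining the
#'   full randomised cohort; defaults to the participants present in
#'   `visits`.
#' @return List with `by_arm` (data.frame `arm`, `abstinent`, `total`),
#'   `pooled_abstinent`, `pooled_total`, `pooled_percent`.
#' @export
abstinence_table <- function(visits, visit = "week12", roster = NULL) {
  if (is.null(roster))
    roster <- unique(visits[, c("participant_id", "arm")])
  rows <- visits[visits$visit == visit, , drop = FALSE]
  abst_ids <- rows$participant_id[vapply(seq_len(nrow(rows)), function(i)
    classify_abstinent(rows[i, , drop = FALSE]), logical(1))]
  roster$abstinent <- roster$participant_id %in% abst_ids
  by_arm <- stats::aggregate(
    cbind(abstinent = roster$abstinent, total = 1L) ~ arm,
    data = roster, FUN = sum)
  pooled_a <- sum(by_arm$abstinent)
  pooled_n <- sum(by_arm$total)
  list(by_arm = by_arm,
       pooled_abstinent = pooled_a, pooled_total = pooled_n,
       pooled_percent = round_half_up(100 * pooled_a / pooled_n))
}

# round half away from zero, as printed percentages conventionally are
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an r x c contingency table, without
#' continuity correction, with df = (r-1)(c-1) and an upper-tail p-value.
#' Delegates to [stats::chisq.test()].
#'
#' @param table Matrix of counts (e.g. arms x outcome).
#' @return List with `statistic`, `df`, `p_value`, and the expected counts.
#' @examples
#' week12 <- rbind(c(6, 21), c(4, 23), c(4, 23))
#' chisq_independence(week12)$p_value   # ~0.71
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chisq_independence: zero row or column marginal")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Computes the one-way fixed-effects F test from per-group (n, mean, SD)
#' triples alone, as needed to reproduce F statistics from published
#' summary tables: between-group sum of squares
#' \eqn{SSB = \sum n_i (m_i - \bar m)^2} about the grand (weighted) mean,
#' within-group sum of squares \eqn{SSW = \sum (n_i - 1) s_i^2}, and
#' \eqn{F = (SSB/(k-1)) / (SSW/(N-k))}.  When the summaries are computed
#' from raw data this reproduces `anova(lm(y ~ group))` exactly.
#'
#' @param groups Data.frame with columns `n`, `mean`, `sd` (one row per
#'   group), or a list of such triples.
#' @return List with `F`, `df_between`, `df_within`, `p_value`.
#' @examples
#' g <- data.frame(n = c(21, 22, 22),
#'                 mean = c(4.33, 3.59, 3.95),
#'                 sd = c(0.66, 1.14, 0.95))
#' anova_from_summary(g)$F   # ~3.3
#' @export
anova_from_summary <- function(groups) {
  g <- as.data.frame(groups)
  stopifnot(all(c("n", "mean", "sd") %in% names(g)))
  if (nrow(g) < 2) stop("anova_from_summary: need at least two groups")
  if (any(g$n < 2)) stop("anova_from_summary: every group needs n >= 2")
  if (any(g$sd < 0)) stop("anova_from_summary: negative SD")
  N <- sum(g$n)
  k <- nrow(g)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  df_b <- k - 1
  df_w <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df_between = df_b, df_within = df_w,
                              p_value = 1))
    stop("anova_from_summary: zero within-group variance with unequal means")
  }
  f <- (ssb / df_b) / (ssw / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Compensation rule for visits and EMA compliance
#'
#' Participants earn a fixed payment per attended visit (USD 30 for each of
#' baseline, quit date and week 4; USD 50 for week 12) plus a bonus tied to
#' the percentage of *prompted* EMAs completed over the 5-week window:
#' 50-74% earns USD 50, 75-89% earns USD 100, and 90% or more earns
#' USD 150.  Self-initiated reports are never compensated.
#'
#' @param visit_payments Named numeric: `baseline`, `quit_date`, `week4`,
#'   `week12`.
#' @param ema_tiers Data.frame with columns `lower`, `upper` (percent band
#'   edges) and `payment`.
#' @return An object of class `compensation_rule`.
#' @export
compensation_rule <- function(visit_payments = c(baseline = 30,
                                                 quit_date = 30,
                                                 week4 = 30, week12 = 50),
                              ema_tiers = data.frame(
                                lower = c(50, 75, 90),
                                upper = c(74, 89, 100),
                                payment = c(50, 100, 150))) {
  o <- order(ema_tiers$lower)
  ema_tiers <- ema_tiers[o, , drop = FALSE]
  if (any(diff(ema_tiers$payment) < 0))
    stop("compensation_rule: tier payments must be nondecreasing")
  if (any(ema_tiers$lower[-1] <= ema_tiers$upper[-nrow(ema_tiers)]))
    stop("compensation_rule: overlapping tiers")
  structure(list(visit_payments = visit_payments, ema_tiers = ema_tiers),
            class = "compensation_rule")
}

#' Compute a participant's compensation
#'
#' The completion percentage is computed exactly and rounded to 0.1% before
#' tier lookup; tier lower bounds are inclusive (exactly 50.0% earns the
#' first bonus) and completion below 50% earns no EMA bonus.
#'
#' @param completed_prompted Prompted EMAs completed.
#' @param scheduled_prompted Prompted EMAs scheduled.
#' @param visits_attended Character vector (or named logical) of attended
#'   visits among `baseline`, `quit_date`, `week4`, `week12`.
#' @param rule A [compensation_rule()].
#' @return Total USD.
#' @examples
#' compensation(158, 175, c("baseline", "quit_date", "week4", "week12"))
#' # 290: 30 + 30 + 30 + 50 visit payments + 150 for 90.3% completion
#' @export
compensation <- function(completed_prompted, scheduled_prompted,
                         visits_attended = character(0),
                         rule = compensation_rule()) {
  if (completed_prompted < 0 || scheduled_prompted < 0)
    stop("compensation: negative counts")
  if (completed_prompted > scheduled_prompted)
    stop("compensation: completed exceeds scheduled")
  if (is.logical(visits_attended))
    visits_attended <- names(visits_attended)[visits_attended]
  visit_total <- sum(rule$visit_payments[visits_attended], na.rm = TRUE)
  pct <- if (scheduled_prompted == 0) 0 else
    round_half_up(100 * completed_prompted / scheduled_prompted, 1)
  tier <- rule$ema_tiers[rule$ema_tiers$lower <= pct, , drop = FALSE]
  bonus <- if (nrow(tier)) tier$payment[nrow(tier)] else 0
  unname(visit_total + bonus)
}

#' Nicotine-patch wear-time category labels
#'
#' @return Character vector of the nine daily wear-time categories, from
#'   none to at least 22-24 hours.
#' @export
patch_categories <- function() {
  names(patch_hours_map)
}

# Category -> midpoint hours.  The three anchors (0, 2, 5) follow the
# stated recoding; the remaining 3-hour bands continue the same
# middle-of-category rule and are reconstructed, not transcribed.
patch_hours_map <- c(
  "I did not wear it at all" = 0,
  "Less than 3 hours" = 2,
  "4-6 hours" = 5,
  "7-9 hours" = 8,
  "10-12 hours" = 11,
  "13-15 hours" = 14,
  "16-18 hours" = 17,
  "19-21 hours" = 20,
  "At least 22-24 hours" = 23
)

#' Recode patch wear-time categories to continuous hours
#'
#' Each daily-diary wear-time category maps to the middle time point of its
#' band (e.g. "4-6 hours" to 5 hours).
#'
#' @param category Character vector of category labels.
#' @return Numeric hours.
#' @export
recode_patch_hours <- function(category) {
  unknown <- setdiff(unique(category[!is.na(category)]),
                     names(patch_hours_map))
  if (length(unknown))
    stop("recode_patch_hours: unknown category label(s): ",
         paste(unknown, collapse = "; "))
  unname(patch_hours_map[category])
}

#' Summaries of delivered messages
#'
#' Tabulates a decision log: counts and proportions by message category,
#' shares of the four trigger-tailored categories among high-risk
#' deliveries, gum prompts per participant, and per-day delivery counts
#' for time-course summaries.
#'
#' @param decisions Decision log from [decide()].
#' @param n_participants Denominator for per-participant means (defaults
#'   to the number of distinct participants in the log).
#' @return List with `by_category`, `high_risk_shares` (percent, summing
#'   to 100 when any high-risk tailored message exists), `total_messages`,
#'   `per_participant_mean`, `gum_prompts`, `gum_per_participant`,
#'   `per_day` counts.
#' @export
message_distribution <- function(decisions,
                                 n_participants =
                                   length(unique(decisions$participant_id))) {
  if (!nrow(decisions)) {
    return(list(by_category = data.frame(category = character(0),
                                         n = integer(0)),
                high_risk_shares = NULL, total_messages = 0L,
                per_participant_mean = NA_real_, gum_prompts = 0L,
                gum_per_participant = NA_real_,
                per_day = data.frame(day = integer(0), n = integer(0))))
  }
  by_cat <- as.data.frame(table(category = decisions$category),
                          stringsAsFactors = FALSE)
  names(by_cat)[2] <- "n"
  hi <- by_cat[grepl("^high_risk_", by_cat$category), , drop = FALSE]
  shares <- if (sum(hi$n) > 0) {
    s <- 100 * hi$n / sum(hi$n)
    names(s) <- sub("^high_risk_", "", hi$category)
    s
  } else NULL
  per_day <- as.data.frame(table(day = decisions$day),
                           stringsAsFactors = FALSE)
  names(per_day)[2] <- "n"
  per_day$day <- as.integer(per_day$day)
  gum <- sum(decisions$gum_prompt)
  list(by_category = by_cat,
       high_risk_shares = shares,
       total_messages = nrow(decisions),
       per_participant_mean = nrow(decisions) / n_participants,
       gum_prompts = gum,
       gum_per_participant = gum / n_participants,
       per_day = per_day)
}
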