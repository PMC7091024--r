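---
title: "Methods: the lapse-risk decision engine, cohort simulator, and trial statistics"
author: "jitair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lapse-risk decision engine, cohort simulator, and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitair)
```

## The intervention model

`jitair` implements a just-in-time adaptive intervention (JITAI) for
smoking cessation.  Participants in a quit attempt carry a phone that
prompts brief ecological momentary assessments (EMAs) five times a day --
four at random times plus one daily diary -- across a 35-day window: 7
days before the scheduled quit date and 28 days after it.  At the
completion of every EMA the engine scores the momentary risk of a smoking
lapse, classifies the moment as low or high risk, and pushes one tailored
treatment message.  The package also provides a synthetic three-arm
cohort generator and the trial-statistics layer needed to analyse such a
study (carbon-monoxide-verified abstinence, chi-square arm comparisons,
summary-statistic ANOVA, compensation accounting), so that every stage is
testable at desk scale with no participant data.

## The risk model

Each assessment reports six lapse antecedents: urge to smoke, stress,
cigarette availability and motivation to avoid smoking on 1-5 Likert
scales, and two binary exposures -- interaction with someone smoking and
alcohol in the last hour.  The motivation item is administered
reverse-coded (1 = strongly agree that one is motivated to avoid smoking),
so a higher raw value already means higher risk.  The momentary risk score
is a weighted sum

$$r = \sum_i w_i x_i, \qquad x_{\text{Likert}} = \frac{v-1}{4}, \quad
x_{\text{binary}} \in \{0,1\},$$

with the weights normalised to sum to one, so $r \in [0,1]$ regardless of
the weight scale, and $r$ is monotone nondecreasing in every factor.  The
factor rescaling to $[0,1]$ is a package design choice: it makes the
score weight-sum invariant and gives the threshold a fixed meaning.

**The weights and the threshold $\tau$ are required configuration, not
constants of the package.**  In the deployed intervention they were
estimated in a prior lapse-prediction study from EMA data preceding
observed lapses; those estimates are not public.  The defaults in
`risk_config()` (urge .25, stress .15, alcohol .05, interaction .15,
motivation .15, availability .25; $\tau = 0.5$) are an illustrative,
non-canonical weighting used for documentation, simulation and testing.

A moment is classified **high risk** when any of the following holds:

1. the weighted score reaches the threshold, $r \ge \tau$;
2. the participant already smoked today or yesterday (tracked from
   self-initiated smoking reports, shifted at each day rollover);
3. on the first daily assessment the participant rated their chance of
   smoking before the end of the day *strictly above* 25%.

The likelihood rule is strict ("greater than 25%"): a rating of exactly
25 does not trigger it.  Whether the over-threshold rating flags the whole
calendar day or only the reporting assessment is not specified by the
protocol; the engine defaults to the whole day (`likelihood_scope =
"day"`) with `"report_only"` available, because a morning rating of one's
chance of smoking *today* naturally scopes to the day.

## Message routing

One message is delivered per completed EMA:

* **Prequit phase** (days 0-6): quit-preparation content, regardless of
  the score.
* **Postquit, low risk**: abstinence-motivation and general-advice
  content.  The protocol does not subdivide this bank; it is a single
  category here.
* **Postquit, high risk**: content tailored to the *highest-rated* of the
  four momentary triggers (urge, stress, availability, motivation --
  reverse-coded motivation compares directly against the others' raw
  ratings), accompanied by a fixed prompt to chew a piece of nicotine
  gum.  Ties between triggers break by a configured priority order,
  defaulting to urge > availability > stress > motivation; urge is the
  most proximal lapse antecedent, so it heads the order.  Comparing the
  reverse-coded motivation rating directly with the other raw ratings is
  an assumption -- the protocol does not state the comparison scale --
  and it is configurable only through the priority order.
* **Postquit, lapsed and no longer interested in quitting**:
  lapse-recovery content framing the lapse as a learning experience.  A
  participant who reports no interest but has *not* lapsed falls back to
  the low-risk bank, which keeps the invariant that trigger-tailored
  content (and the gum prompt) appears only in interested, high-risk,
  postquit moments.

Within a category the least-recently-delivered message is chosen (bank
order breaks ties), so content rotates rather than repeats; the protocol
is silent on repetition and this is the package's choice.  Day-level
treatment messages (e.g. quit-date reminders) are a separate bank
category and are additional to, not replacements for, EMA-completion
messages.

## The prompt schedule

The daily diary is placed at the start of the waking window so that "the
first daily assessment" is well defined; the four random prompts are
drawn uniformly over the window subject to a minimum gap between any two
same-day prompts, the diary included.  The waking window (08:00-22:00)
and minimum gap (40 min) are unstated in the protocol and configurable;
the defaults are conventional for five-prompt EMA designs.  Scheduling is
rejection sampling, which is exact and cheap at these sizes (the
feasibility precondition `window >= 5 * min_gap` guarantees termination
with high acceptance rates at the defaults).  A schedule is fully
determined by its seed.

## The synthetic cohort generator

The generator is first-class, tested code whose defaults *are* the study
conditions the package assumes; it is not tuned per analysis.

* **Cohort**: 27 participants per arm in three arms (Smart-T2 app,
  comparison app, usual care), 81 in total, mirroring the pilot-trial
  cohort.
* **Compliance**: each participant answers any scheduled prompt with a
  personal probability drawn once from Beta(8.4, 1.6), whose mean of 0.84
  mirrors the reported 84.0% prompted-EMA compliance.  The pooled
  completion rate uses prompts *before* a participant's withdrawal as its
  denominator; published compliance figures are consistent with a
  denominator adjusted for withdrawal, and post-withdrawal prompts are
  simply absent from the simulated log.
* **Items**: Likert responses are discretised latent normals (draw,
  round, clamp to 1..5) with item-specific means and SDs (urge 2.8/1.2,
  stress 2.5/1.2, availability 3.2/1.3, motivation 2.0/1.0).  The
  protocol gives no response-generating model; the latent-normal choice
  yields controllable ordinal marginals, with availability set highest so
  that availability dominates the trigger mix, as it did in the deployed
  intervention.  Binary exposures are Bernoulli (smoker interaction 0.2,
  alcohol 0.1).
* **First-daily likelihood**: normal around
  $100\,\mathrm{logit}^{-1}(\alpha + \beta r)$ with SD 15, truncated to
  [0, 100] -- participants' self-rated chance of smoking tracks their
  modelled risk, noisily.
* **Lapse process**: after each answered postquit assessment with score
  $r$, a lapse occurs with probability
  $\mathrm{logit}^{-1}(\alpha + \beta r)$, and is self-reported exactly 5
  minutes later; the fixed offset lets (score, lapse) pairs be recovered
  from the serialised log alone (`lapse_pairs()`), so the logistic model
  is refittable from the CSV a run writes.  Defaults $\alpha = -4$,
  $\beta = 3$ give roughly a 2-6% per-assessment lapse probability over
  the typical score range -- a rate a field EMA study would call
  realistic -- while parameter-recovery checks use the steeper
  $\alpha = -2$ operating point at which recovery tolerances are stated.
* **Dropout**: geometric with per-day hazard 0.0044, matching roughly a
  third of participants withdrawing over 13 weeks; visits after the
  dropout day are absent, EMA rows after it do not exist.
* **Visits and CO**: abstinence at the quit-date and week-4 visits is
  no-lapse-in-window from the simulated lapse stream; week-12 abstinence
  persists from week 4 with probability 0.75 (0.05 for late quitting).
  Expired CO is Gaussian around 3 ppm (abstinent) or 15 ppm (smoking),
  SD 1.5, truncated at zero; smokers falsely self-report abstinence with
  probability 0.1 and are caught by the CO cutoff.  Only the
  classification cutoffs (below 6 ppm; below 10 ppm on the quit date)
  are protocol-fixed; the CO level model is the package's own and is
  configurable.

One global seed fans out to per-participant substreams
(`seed + 1000003 * index`, reduced mod $2^{31}-1$), so a participant can
be regenerated in isolation and identical configurations reproduce every
output file byte for byte.

What the generator does **not** emulate: within-day autocorrelation and
diurnal cycles in the items, item-level missingness within an answered
assessment, reactive effects of message delivery on subsequent risk (no
treatment effect exists in the simulator: arms differ only in label), and
intermittent missed visits separate from dropout.  Passing tests
therefore demonstrate the correctness of the engine and statistics on
data with the assumed structure, not effectiveness claims about real
cohorts.

## Trial statistics

* **Abstinence** is intent-to-treat 7-day point prevalence: abstinent
  requires a no-puff self-report *and* CO strictly below 6 ppm (10 ppm at
  the quit date); anything missing -- visit, self-report or reading --
  counts as smoking.  Pooled percentages round half-up to integers, the
  convention of published abstinence tables.
* **Chi-square** arm comparisons use the Pearson statistic without
  continuity correction, df $(r-1)(c-1)$, upper-tail p; the
  implementation delegates to `stats::chisq.test(correct = FALSE)` and is
  tested against the textbook $\sum (O-E)^2/E$ formula.
* **ANOVA from summaries** reconstructs the one-way F test from per-group
  (n, mean, SD) alone: $SSB = \sum n_i(m_i - \bar m)^2$ about the
  weighted grand mean, $SSW = \sum (n_i - 1) s_i^2$,
  $F = (SSB/(k-1))/(SSW/(N-k))$.  When summaries come from raw data this
  equals `anova(lm(y ~ group))` to machine precision (property-tested);
  when they come from a published table rounded to two decimals, the
  reconstructed F lands within about $\pm 0.15$ of the printed value.
* **Compensation**: USD 30 per attended baseline/quit-date/week-4 visit,
  USD 50 for week 12, plus an EMA bonus by completion band -- 50-74%:
  USD 50, 75-89%: USD 100, >= 90%: USD 150.  The completion percentage is
  rounded to 0.1% before band lookup and band lower edges are inclusive,
  reading the printed integer band edges as inclusive lower bounds;
  self-initiated reports never enter the numerator.
* **Patch wear-time recoding** maps each diary category to its band
  midpoint (none = 0 h, "Less than 3 hours" = 2 h, "4-6 hours" = 5 h, ...,
  "At least 22-24 hours" = 23 h).  Only the first three anchors are
  protocol-stated; the remaining 3-hour bands continue the same
  middle-of-category rule and the full label set is a documented
  reconstruction.
* **Message distributions** report per-category counts, the share of each
  trigger among high-risk tailored deliveries, gum prompts per
  participant, and per-day counts for time-course summaries.  An empty
  log yields zero counts and undefined (flagged `NULL`) shares.

## Numerical and degenerate-input choices

p-values are upper-tail for both $\chi^2$ and F; no multiple-testing
correction is applied (none is in the analysis this mirrors).  Zero
within-group variance with unequal means is an error rather than an
infinite F; equal means with zero variance returns F = 0.  A zero row or
column marginal is a chi-square error.  Floating-point output in CSV and
decision logs is fixed at 6 decimal places so reruns are byte-stable.
Day indexing is 0-based from baseline with minutes-from-midnight times
and no timezone logic; self-initiated responses never count toward
prompted-EMA compliance.

## Problem sizes used in the checks

The test-suite and the acceptance script exercise: the published summary
tables as-is (deterministic); the engine oracles over the full factor
grid (90,000 combinations x 100 random configurations) and all 625
trigger-rating combinations; compliance recovery on 500 simulated
participants (tolerance 2 percentage points around the Beta mean of
84%); lapse-slope recovery on roughly 7,000 assessment pairs from 60
participants at the $\alpha=-2, \beta=3$ operating point (tolerance
$\pm 0.3$ on the slope); and full 81-participant pipeline runs.  These
sizes give Monte-Carlo error comfortably inside the stated tolerances
while keeping a complete run in minutes on one core.

## Command-line interface

`inst/cli/jitair` is a thin Rscript wrapper exposing `simulate`,
`decide`, `analyze`, `anova-summary`, `run` and `validate` subcommands
over the exported functions, with exit code 0 on success, 2 on validation
failure and 3 on runtime failure.  The R functions, not the CLI, are the
primary interface.
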