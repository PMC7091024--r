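# jitair

A just-in-time adaptive intervention (JITAI) decision engine for smoking
cessation, with a synthetic trial simulator and the statistics layer of a
three-arm cessation trial.

Smoking lapses cluster around identifiable momentary states -- strong
urges, stress, easy cigarette access, low motivation, alcohol, other
people smoking.  A JITAI monitors those states through brief ecological
momentary assessments (EMAs, five per day over a 35-day quit window) and
pushes a tailored treatment message at the completion of every
assessment.  `jitair` implements that engine end to end, plus everything
needed to exercise it without participant data:

* **EMA core** -- the study calendar (7 prequit + 28 postquit days),
  seeded prompt scheduling (4 random + 1 daily diary per day with a
  minimum gap), response validation, and participant-state replay.
* **Decision engine** -- the weighted lapse-risk score
  `r = Σ wᵢxᵢ` over six rescaled factors; high-risk classification
  (`r ≥ τ`, or smoked today/yesterday, or a first-daily self-rated chance
  of smoking today strictly above 25%); trigger-tailored message
  selection with least-recently-used rotation; a nicotine-gum prompt at
  high-risk moments; engagement-event logging.
* **Synthetic cohort** -- a fully seeded 3 × 27 trial generator with
  Beta-distributed compliance, latent-normal Likert items, a logistic
  risk-linked lapse process, dropout, and CO-verified visits.
* **Trial statistics** -- intent-to-treat CO-verified abstinence tables,
  Pearson chi-square arm comparisons, one-way ANOVA reconstructed from
  published (n, mean, SD) summaries, compliance-tier compensation, patch
  wear-time recoding, and message-distribution summaries.

The risk-formula weights and threshold are **required configuration**:
they come from prior lapse-prediction work and are not published
constants.  The package defaults are an illustrative weighting, clearly
labelled non-canonical.

## Worked example

```r
library(jitair)

# score one assessment: urge 5/5, stress 3/5, cigarettes easily available
# (4/5), motivation item 2 (reverse-coded), interacting with a smoker
cfg <- risk_config()   # illustrative weights: urge .25, stress .15, ...
r <- ema_response(urge = 5, stress = 3, availability = 4, motivation = 2,
                  with_smoker = 1, alcohol = 0)
compute_risk_score(r, cfg)
#> [1] 0.7
classify_risk(list(smoked_today = FALSE, smoked_yesterday = FALSE,
                   first_daily_likelihood = NA), r, cfg)
#> [1] "high"
select_trigger(r)
#> [1] "urge"
```

The score 0.70 is the weighted sum of the rescaled factors
(.25·1 + .15·0.5 + .05·0 + .15·1 + .15·0.25 + .25·0.75); it clears the
default threshold τ = 0.5, so the moment is high risk and the message is
tailored to the highest-rated trigger (urge, 5/5), accompanied by a
nicotine-gum prompt.

Rebuild a one-way ANOVA from a published summary row (three treatment
groups' satisfaction ratings, n/mean/SD only):

```r
anova_from_summary(data.frame(n = c(21, 22, 22),
                              mean = c(4.33, 3.59, 3.95),
                              sd = c(0.66, 1.14, 0.95)))
#> F = 3.32 on df (2, 62), p = 0.043
chisq_independence(rbind(c(6, 21), c(4, 23), c(4, 23)))
#> chi-square = 0.69, df = 2, p = 0.71
```

Run the full seeded pipeline (simulate → decide → analyze) on a small
cohort:

```r
run <- load_config(list(seed = 7, sim = list(n_per_arm = 5)))
run_pipeline(run, "demo")
rep <- jsonlite::fromJSON("demo/report.json")
#> participants: 15
#> EMA completion: 77.4%
#> week-12 abstinent: 1 / 15
#> high-risk shares (%): availability 37.2, motivation 3.1, stress 12.8, urge 46.9
#> gum prompts per participant: 51.6
```

The output directory holds `ema.csv`, `visits.csv`, `events.jsonl`,
`decisions.jsonl`, `report.json` and a `provenance.json` with the
effective configuration, seed and per-file checksums; rerunning the same
configuration reproduces every file byte for byte.  A thin command-line
wrapper with `simulate`, `decide`, `analyze`, `anova-summary`, `run` and
`validate` subcommands ships in `inst/cli/jitair`.

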