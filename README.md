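# cpraid

Scoring and analysis of cardiopulmonary-resuscitation (CPR) guideline
conformance from timestamped resuscitation event logs, with a simulation
model of an advanced-life-support (ALS) cognitive aid.

Resuscitation teams are expected to follow a tightly timed algorithm:
continuous chest compressions with minimal interruptions, a rhythm check and
compressor change every 2 minutes, adrenaline every 3–5 minutes, and
amiodarone after the third defibrillation. Studies of team performance —
for example randomized simulation trials of tablet-based cognitive aids —
quantify conformance by coding each videotaped scenario into an event log
and scoring a fixed set of performance variables against guideline margins.
`cpraid` implements that measurement chain end to end for researchers in
resuscitation science and simulation-based education:

- **Event model** — validated event logs (compressions, rhythm checks,
  defibrillations, drug administrations, ROSC), compression-quality series,
  and cohort manifests, all with plain-text round-trip serialization.
- **Cognitive-aid engine** — a deterministic state machine producing the
  aid's timer alerts (rhythm check due, compressor change, adrenaline due,
  amiodarone after the third shock) and logging user interactions.
- **Metrics** — no-flow fraction, times to first rhythm check/shock,
  cycle-deviation measures, drug counts and deviations, amiodarone class.
- **Scoring** — a configurable rubric awarding 0/1/2 per variable with
  margin bands derived from a 15% tolerance rule; the CPR performance score
  is the mean over the non-missing variables (12, or 10 when
  compression-quality data are unavailable).
- **Statistics** — absolute-agreement intraclass correlation ICC(A,1),
  normality-gated two-group comparison (t test or Mann–Whitney U with
  rank-biserial effect size), Fisher's exact test, raw NASA-TLX, and
  two-group sample-size computation.
- **Synthetic data** — a seeded team-behavior simulator (event-level) and a
  calibrated scorecard sampler (distribution-level) for testing and power
  exploration.
- **Pipeline** — manifest/generator → metrics → scorecards → group tables
  and comparisons, with reproducible on-disk reports, plus an inter-coder
  reliability check.

## The score in one paragraph

Each team's scenario is reduced to 12 performance variables. Continuous
variables are banded: values within the guideline target score 2, values
within a 15% margin above it score 1, worse values score 0 (for the 120 s
rhythm-check target this yields the 120 s / 138 s edges and, applied to the
cycle-deviation scale, 18 s / 36 s bands). Count variables compare observed
with expected actions; adrenaline-interval deviation is all-or-nothing;
amiodarone is scored categorically (after third shock / given / none). The
CPR performance score is the unweighted mean of the non-missing variable
scores, so it lives on the same 0–2 scale.

## Worked example

```r
library(cpraid)

# simulate one aided team, compute its metrics, score it
sim  <- simulate_team_log(behavior_config("CA_APP", seed = 7),
                          team_seed = 1, team_id = "demo")
perf <- compute_performance(sim$log, sim$series)
round(perf$no_flow_fraction, 1)   # percent of arrest time without compressions
#> [1] 9.8
score_team(perf)
#> <cpr_scorecard> team demo: CPR performance score 1.25 over 12 variables

# a full two-arm study: 32 aided vs 31 unaided teams
res <- run_pipeline(run_config(generator = list(
  behavior_config("CA_APP", seed = 2024),
  behavior_config("NO_APP", seed = 2025))))
res
#> <cohort_result> CA_APP: 32, NO_APP: 31 team(s)
#> MANN_WHITNEY: statistic = 799.500, p = 2.814e-05, rank_biserial = 0.612

aggregate(cpr_score ~ group, res$scorecard_table,
          function(x) round(c(mean = mean(x), sd = sd(x)), 2))
#>    group cpr_score.mean cpr_score.sd
#> 1 CA_APP           1.18         0.21
#> 2 NO_APP           0.87         0.29
```

Event logs, compression series, rubrics (YAML) and manifests all
round-trip through plain-text files; see `?write_event_log`,
`?write_rubric`, `?simulate_cohort` and `?run_pipeline`.

## Vignette

`vignettes/cpr-conformance-methods.Rmd` documents the measurement model,
the rubric and its parameters, the synthetic generator's calibration and
limits, and the numerical conventions.
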