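---
title: "Measuring CPR guideline conformance: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CPR guideline conformance: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the measurement model implemented by `cpraid`, the
meaning and defaults of its parameters, how the synthetic generator
emulates team behaviour (and where it deliberately does not), and the
numerical conventions that affect results at the margins.

## 1. The measurement model

### Event logs

A scenario is represented as a `cpr_event_log`: a team identifier, study
arm (`CA_APP` = aided by the cognitive-aid app, `NO_APP` = unaided), an
arrival time (when the team reaches the patient), a scenario end, an
optional time of return of spontaneous circulation (ROSC), and a
time-sorted table of events. Nine event kinds are modelled: compression
start/stop, rhythm-check start/end, defibrillation, compressor change,
adrenaline, amiodarone, and ROSC. Validation (`validate_log()`) enforces
sorted timestamps, bounds within `[0, scenario_end]`, strict alternation
of compression start/stop, pairing of rhythm-check start/end, and that
events do not precede arrival. All timestamps are in seconds from scenario
start.

Compression quality is a separate, optional `cpr_compression_series`:
per-period mean depth (cm) and mean rate (per minute). It is optional
because the measurement device can fail to export; teams without it are
scored on ten instead of twelve variables (below).

### The twelve performance variables

`compute_performance()` reduces a log (plus optional series) to:

1. `no_flow_fraction` — percentage of the arrest interval without ongoing
   compressions. The arrest interval runs from arrival to
   `min(rosc_time, scenario_end)`.
2. `avg_depth`, `avg_rate` — duration-weighted means of the compression
   series (missing when the series is unavailable).
3. `t_first_rhythm`, `t_first_shock` — seconds from arrival to the first
   rhythm check / defibrillation (`t_first_shock` may be `NA` if the team
   never defibrillates; the rubric scores that as 0).
4. `n_rhythm_checks`, `n_compressor_changes`, `n_adrenaline` — counts.
5. `dev_rhythm`, `dev_compressor_change` — mean one-sided cycle deviation:
   for consecutive intervals between the events (the first measured from
   arrival), the mean of `max(0, interval − 120 s)`. Only lateness counts;
   checking early is not penalised.
6. `dev_adrenaline` — mean distance of inter-dose intervals from the
   `[180 s, 300 s]` guideline window (the first dose is exempt, since no
   prior dose anchors its interval).
7. `amiodarone_class` — `AFTER_THIRD_SHOCK` (first amiodarone after the
   third defibrillation), `GIVEN` (given, but not in that position), or
   `NONE`.

### The rubric and the CPR performance score

Each variable is awarded 0, 1 or 2 points by `score_team()` against a
configurable rubric (`default_rubric()`, serialisable to YAML):

* **Margin bands** (`upper_bands`). The guideline threshold scores 2 up to
  and including the threshold; a 15% margin above it scores 1; anything
  worse scores 0. `margin_bands(120, 0.15)` gives the 120 s / 138 s edges
  used for times-to-first-event, and `deviation_bands(120, 0.15)` rescales
  the same rule to the deviation metrics, giving 18 s / 36 s (15% and 30%
  of the 120 s cycle). No-flow fraction uses 15% / 20% band edges.
* **Target ranges** (`target_range`): depth 5–6 cm, rate 100–120 per
  minute score 2, anything outside scores 0 (no intermediate band — a
  compression that is too shallow by a little is still ineffective).
* **Zero-only** (`zero_only`): adrenaline-window deviation scores 2 only
  at zero deviation (within a 1e-9 s floating-point guard), otherwise 0.
* **Expected counts** (`expected_count`): observed ≥ expected scores 2,
  one short scores 1, otherwise 0, with expectations derived from the
  scenario length (one rhythm check and compressor change per started
  120 s cycle, one adrenaline dose per started 240 s).
* **Categorical**: amiodarone `AFTER_THIRD_SHOCK`/`GIVEN`/`NONE` → 2/1/0.

Missing values are handled per variable (`absent` policy): depth/rate are
genuinely missing (team scored on 10 variables), a missing first shock is
scored worst, and a missing deviation (fewer than one measurable interval)
contributes zero deviation.

The **CPR performance score** is the unweighted mean of the non-missing
variable scores, so it lives on the same 0–2 scale. A team may miss at
most the two compression-quality variables; more missingness is an error,
not a silently shrunken denominator.

### Group statistics

`compare_groups()` gates on normality (Kolmogorov–Smirnov with Lilliefors
correction, per group, n ≥ 5) and runs either a two-sample t test (pooled
SD, Cohen's d) or a Mann–Whitney U test with the rank-biserial correlation
`1 − 2U/(n_a·n_b)` as effect size — equivalently the difference between
the proportions of pairs favouring each group. `icc_a1()` implements the
single-rater, absolute-agreement intraclass correlation ICC(A,1) from the
two-way ANOVA mean squares, with an F-based confidence interval using
Satterthwaite degrees of freedom; `reliability_check()` applies it to two
coders' values of the six continuous reliability variables.
`fisher_exact()`, `tlx_raw()` (mean of the six NASA-TLX subscales) and
`sample_size_two_group()` (normal-approximation two-group size for a
standardised difference) round out the toolbox.

## 2. Parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `cycle_target` | 120 | s | ALS rhythm-check / compressor-change cycle |
| `adrenaline_window` | 180–300 | s | "every 3–5 minutes" |
| `margin` | 0.15 | — | tolerated overshoot before losing a point |
| `rhythm_prepare` (aid) | 100 | s | early warning ahead of the 120 s alert |
| `rhythm_due` (aid) | 120 | s | cycle due alert |
| `adrenaline_consider` (aid) | 180 | s | lower edge of the dosing window |
| depth range | 5–6 | cm | guideline compression depth |
| rate range | 100–120 | /min | guideline compression rate |

`sample_size_two_group(d = 0.7)` returns 33 per group at α = 0.05 and
power 0.8; power is an explicit parameter rather than a constant because
reported power conventions vary (0.8 and 0.9 are both common; 0.9 yields
2 × 33 for d = 0.8).

## 3. The synthetic generator

Two generators serve different purposes.

### The calibrated scorecard sampler

`sample_scorecards()` draws each team's per-variable score independently
from a per-variable distribution over {0, 1, 2} (the bundled calibration,
`inst/extdata/default_score_calibration.csv`, reflects score proportions
observed in a randomized two-arm simulation study: 32 aided teams with 5
missing compression data, 31 unaided with 9). It reproduces cohort-level
score distributions and the implied group means by construction
(`expected_cohort_score()` computes the exact expectation: Σ k·p(k) per
variable, averaged over 12 or 10 variables, weighted by the number of
teams with and without compression data). What it does **not** model:
correlations between variables within a team (a slow team is likely slow
on several clocks at once), so team-level score variances are
underestimated relative to real cohorts.

### The mechanistic team simulator

`simulate_team_log()` generates a full, always-valid event log for a
persistent shockable rhythm. Behaviour is parameterised by
`behavior_config()`; latency and drift distributions are normals truncated
below at zero (deviations in this domain are one-sided — teams run late,
not early, relative to the 120 s cycle). The per-arm defaults (e.g. mean
cycle drift 12 s aided vs 31 s unaided, first rhythm check after 74 s vs
98 s, scenario length 943 s vs 902 s) are calibrated so that cohort-level
raw summaries approximate aided and unaided team behaviour; they are
plausible behaviour, not measured ground truth.

Design choices worth knowing:

* **No boundary censoring.** The number of rhythm cycles follows from the
  nominal scenario length and the scenario end extends to cover the
  drifted schedule. The alternative — generating cycles until the scenario
  boundary cuts them off — length-biases the accepted intervals (long
  drifts get discarded) and would make the configured drift unrecoverable
  from the output. The parameter-recovery test checks exactly this: the
  measured mean cycle deviation at n = 200 teams lies within two standard
  errors of the configured truncated-normal mean.
* **Aided teams drive the real aid engine.** Their interaction log is
  produced by stepping the actual `aid_init()`/`aid_advance()`/
  `aid_press()` state machine through the scenario, not by sampling
  interaction counts.
* **What it does not emulate:** ROSC-driven early termination unless
  configured; non-shockable rhythms; within-scenario learning or fatigue
  trends; ventilation; team-size effects. Compression depth/rate are
  drawn i.i.d. per inter-check period around the team mean.

The score distributions produced by the mechanistic simulator are *not*
calibrated to match the scorecard sampler's; the simulator's contract is
directional (aided cohorts outscore unaided cohorts in at least 95% of
seeded replications) and structural (valid logs, recoverable parameters),
not distribution-exact.

### Seeding

All randomness flows from explicit seeds through `withr::with_seed`, so no
call disturbs the caller's RNG state. Per-team seeds derive from the
master seed as `(seed·1009 + i·7919) mod (2^31 − 1)`, keeping them in
integer range and distinct across teams and arms.

## 4. Numerical conventions

* **Half-open compression intervals.** A compression period `[start, stop)`
  contributes flow time `stop − start`; a trailing unmatched start is
  closed at the end of the arrest window.
* **Arrest window** = `[arrival, min(rosc, scenario_end)]`. All metrics are
  arrival-anchored, making every quantity invariant under a common time
  translation of the log (tested property). `scenario_length` is therefore
  `scenario_end − arrival_time`.
* **Band edges are inclusive for the better score**: a value exactly on
  120 s scores 2; exactly on 138 s scores 1. The rubric stores edges, the
  scorer applies `<=`.
* **Deviations are one-sided** (`max(0, interval − target)`): early action
  is not penalised. A team with fewer than one measurable interval
  contributes zero deviation rather than missing, so the denominator of
  the CPR score stays interpretable.
* **The zero-only adrenaline band** uses a 1e-9 s tolerance purely as a
  floating-point guard, not as a clinical margin.
* **Serialisation** writes doubles with 17 significant digits (`%.17g`) so
  files round-trip bit-exactly; fewer digits can re-order values that
  share a boundary (e.g. the last event vs the scenario end).
* **Rounding** of reported means to 2 decimals happens only at the
  reporting edge; all internal arithmetic is double precision.

## 5. Problem sizes exercised in tests

The test suite runs the metrics against independent oracles on 500 random
logs, sweeps every rubric band edge, compares the rank-biserial statistic
with an exhaustive pairwise-dominance computation for all group sizes up
to 5, verifies ICC(A,1) against a hand-computed ANOVA fixture, recovers
generator parameters at n = 200 teams, checks end-to-end directionality
over 100 two-arm replications of 63 teams, and averages 1,000 sampled
cohorts of 32 scorecards. Everything completes in a few minutes on one
CPU.

## 6. Limitations

The package measures conformance to a fixed, scripted ALS algorithm for a
shockable rhythm; it does not model rhythm transitions, team communication
quality, or clinical outcomes. The bundled calibration is one study's
cohort — users analysing their own data should treat it as a worked
example and supply their own rubric and calibration where conventions
differ.
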