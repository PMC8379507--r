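#' Calibration table for the score sampler
#'
#' Per group and variable: the probabilities of scoring 0, 1 and 2, the
#' mean/SD of the raw variable where one exists, the group size and the
#' number of teams whose compression data are missing. The bundled default
#' (`inst/extdata/default_score_calibration.csv`) reproduces the score
#' distributions observed in a randomized high-fidelity simulation
#' evaluation of a cognitive-aid app in aided (`CA_APP`, 32 teams, 5 without
#' compression data) and unaided (`NO_APP`, 31 teams, 9 without) arms; it is
#' calibration, not ground truth, and is shipped as an editable file.
#'
#' @param path optional path to a calibration CSV with columns `group`,
#'   `variable`, `p0`, `p1`, `p2` (percentages), `mean`, `sd`; default uses
#'   the bundled file.
#' @param group_sizes named integer vector of teams per group.
#' @param n_missing named integer vector of teams without compression data
#'   per group.
#' @return object of class `cpr_calibration`: `distributions` (data frame),
#'   `group_sizes`, `n_missing`.
#' @export
calibration_table <- function(path = NULL,
                              group_sizes = c(CA_APP = 32L, NO_APP = 31L),
                              n_missing = c(CA_APP = 5L, NO_APP = 9L)) {
  if (is.null(path))
    path <- system.file("extdata", "default_score_calibration.csv",
                        package = "cpraid", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "variable", "p0", "p1", "p2")
  if (!all(need %in% names(d)))
    stop_arg("calibration file must have columns %s", paste(need, collapse = ", "))
  sums <- d$p0 + d$p1 + d$p2
  if (any(abs(sums - 100) > 1))
    stop_arg("score percentages of '%s' (%s) sum to %.1f, not 100",
             d$variable[which.max(abs(sums - 100))],
             d$group[which.max(abs(sums - 100))], max(sums))
  if (any(n_missing > group_sizes[names(n_missing)]))
    stop_arg("n_missing cannot exceed the group size")
  structure(list(distributions = d, group_sizes = group_sizes,
                 n_missing = n_missing),
            class = "cpr_calibration")
}

#' Sample a cohort of scorecards from calibrated score distributions
#'
#' The statistical twin of a scored cohort: each team's score on each
#' variable is drawn independently from that variable's (p0, p1, p2), and a
#' configured number of randomly chosen teams has depth/rate set missing and
#' is scored over the remaining ten variables. Reproducible under `seed`.
#'
#' @param cal a [calibration_table()].
#' @param group which group's distributions to sample from.
#' @param seed integer seed.
#' @param n_teams cohort size; default the calibrated group size.
#' @param n_missing teams without compression data; default calibrated.
#' @return list of `cpr_scorecard` objects.
#' @export
sample_scorecards <- function(cal, group = c("CA_APP", "NO_APP"), seed,
                              n_teams = NULL, n_missing = NULL) {
  group <- match.arg(group)
  n_teams <- n_teams %||% unname(cal$group_sizes[group])
  n_missing <- n_missing %||% unname(cal$n_missing[group])
  if (n_missing > n_teams) stop_arg("n_missing cannot exceed n_teams")
  d <- cal$distributions[cal$distributions$group == group, ]
  d <- d[match(PERFORMANCE_VARIABLES, d$variable), ]
  if (anyNA(d$variable)) stop_arg("calibration lacks variables for group %s", group)
  P <- as.matrix(d[, c("p0", "p1", "p2")])
  P <- P / rowSums(P)
  with_seed(seed, {
    miss <- sample.int(n_teams, n_missing)
    lapply(seq_len(n_teams), function(i) {
      scores <- vapply(seq_len(nrow(P)), function(v)
        sample(0:2, 1, prob = P[v, ]), integer(1))
      names(scores) <- PERFORMANCE_VARIABLES
      if (i %in% miss) scores[c("avg_depth", "avg_rate")] <- NA_integer_
      score_card(sprintf("SIM%03d", i), scores, group = group)
    })
  })
}

#' Behavioural configuration for the mechanistic team simulator
#'
#' Defines the timing behaviour of a simulated team facing a persistent
#' shockable rhythm (ventricular fibrillation). All latency/drift
#' distributions are normals truncated below at zero, because cycle
#' deviations are one-sided. The group defaults are calibrated so that
#' cohort-level raw summaries approximate those of aided and unaided teams
#' in a randomized simulation study (e.g. mean rhythm-cycle deviation about
#' 12 s aided vs 31 s unaided); they are plausible behaviour, not measured
#' ground truth.
#'
#' @param group study arm; selects the default parameter set.
#' @param n_teams number of teams to simulate.
#' @param seed master seed.
#' @param scenario_length_mean,scenario_length_sd scenario length after
#'   arrival, seconds.
#' @param arrival_mean,arrival_sd time from scenario start to arrival at the
#'   patient, seconds.
#' @param initial_delay_mean,initial_delay_sd arrival to first compression,
#'   seconds.
#' @param first_check_mean,first_check_sd arrival to first rhythm check,
#'   seconds.
#' @param cycle_drift_mean,cycle_drift_sd extra delay added to the 120 s
#'   rhythm cycle (the aided response latency, or the unaided drift).
#' @param change_drift_mean,change_drift_sd extra delay on the compressor
#'   change cycle.
#' @param pause_mean,pause_sd compression pause around each rhythm check,
#'   seconds.
#' @param first_dose_mean,first_dose_sd arrival to first adrenaline dose.
#' @param adrenaline_interval_mean,adrenaline_interval_sd inter-dose
#'   interval, seconds.
#' @param depth_mean,depth_sd,rate_mean,rate_sd compression quality.
#' @param p_missing_compression probability the simulator export fails.
#' @param amiodarone_compliance probability amiodarone is given after the
#'   third shock.
#' @param p_defib_per_check probability a rhythm check ends in a shock.
#' @param rosc_time optional ROSC time (seconds from scenario start), `NA`
#'   for none.
#' @return a list of class `behavior_config`.
#' @export
behavior_config <- function(group = c("CA_APP", "NO_APP"),
                            n_teams = if (group == "CA_APP") 32L else 31L,
                            seed = 1L,
                            scenario_length_mean = if (group == "CA_APP") 943 else 902,
                            scenario_length_sd = if (group == "CA_APP") 146 else 109,
                            arrival_mean = 20, arrival_sd = 5,
                            initial_delay_mean = if (group == "CA_APP") 15 else 20,
                            initial_delay_sd = if (group == "CA_APP") 5 else 8,
                            first_check_mean = if (group == "CA_APP") 74 else 98,
                            first_check_sd = if (group == "CA_APP") 30 else 53,
                            cycle_drift_mean = if (group == "CA_APP") 12 else 31,
                            cycle_drift_sd = if (group == "CA_APP") 11 else 31,
                            change_drift_mean = if (group == "CA_APP") 29 else 59,
                            change_drift_sd = if (group == "CA_APP") 28 else 68,
                            pause_mean = if (group == "CA_APP") 15 else 16,
                            pause_sd = if (group == "CA_APP") 5 else 6,
                            first_dose_mean = 180, first_dose_sd = 60,
                            adrenaline_interval_mean = if (group == "CA_APP") 250 else 280,
                            adrenaline_interval_sd = if (group == "CA_APP") 80 else 120,
                            depth_mean = if (group == "CA_APP") 4.6 else 4.0,
                            depth_sd = 1.0,
                            rate_mean = if (group == "CA_APP") 121 else 119,
                            rate_sd = if (group == "CA_APP") 7 else 12,
                            p_missing_compression = if (group == "CA_APP") 5 / 32 else 9 / 31,
                            amiodarone_compliance = if (group == "CA_APP") 0.813 else 0.742,
                            p_defib_per_check = 1,
                            rosc_time = NA_real_) {
  group <- match.arg(group)
  cfg <- as.list(environment())
  sds <- grepl("_sd$", names(cfg))
  if (any(unlist(cfg[sds]) < 0)) stop_arg("all SDs must be non-negative")
  if (n_teams < 1) stop_arg("n_teams must be at least 1")
  if (p_missing_compression < 0 || p_missing_compression > 1 ||
      amiodarone_compliance < 0 || amiodarone_compliance > 1 ||
      p_defib_per_check < 0 || p_defib_per_check > 1)
    stop_arg("probabilities must lie in [0, 1]")
  structure(cfg, class = "behavior_config")
}

#' Simulate one team's resuscitation
#'
#' Generates a valid event log for a persistent shockable rhythm: rhythm
#' checks every 120 s plus the configured latency/drift, compression pauses
#' around each check, a defibrillation at the end of each (shockable) check,
#' compressor changes on their own drifted cycle, adrenaline doses at the
#' configured intervals, and amiodarone shortly after the third shock with
#' the configured compliance. Aided (`CA_APP`) teams additionally drive an
#' [aid_init()] state through the scenario, documenting every action plus
#' occasional other interactions, and the button presses are returned as an
#' interaction log.
#'
#' @param cfg a [behavior_config()].
#' @param team_seed integer seed for this team.
#' @param team_id identifier (default derived from the seed).
#' @return list with `log` (a valid `cpr_event_log`), `series` (a
#'   `cpr_compression_series`, possibly unavailable) and `interactions`
#'   (data frame of button presses; `NULL` for unaided teams).
#' @export
simulate_team_log <- function(cfg, team_seed, team_id = sprintf("T%06d", team_seed %% 1000000L)) {
  with_seed(team_seed, {
    arrival <- rtruncnorm(1, cfg$arrival_mean, cfg$arrival_sd)
    len <- rtruncnorm(1, cfg$scenario_length_mean, cfg$scenario_length_sd,
                      lower = 300)

    # rhythm checks: first at arrival + first-check delay, then 120 s plus
    # drift per cycle. The number of cycles follows from the nominal scenario
    # length; a slow team's scenario runs correspondingly longer, so drifted
    # intervals are never censored at the scenario boundary.
    fc_delay <- min(rtruncnorm(1, cfg$first_check_mean, cfg$first_check_sd,
                               lower = 10), len - 60)
    n_checks <- max(1L, as.integer((len - fc_delay - 60) %/% 120))
    drifts <- if (n_checks > 1)
      rtruncnorm(n_checks - 1, cfg$cycle_drift_mean, cfg$cycle_drift_sd)
    else numeric(0)
    checks <- arrival + fc_delay + c(0, cumsum(120 + drifts))
    scen_end <- max(arrival + len, checks[n_checks] + 50)
    horizon <- if (!is.na(cfg$rosc_time)) min(cfg$rosc_time, scen_end) else scen_end
    checks <- checks[checks <= horizon - 45]
    if (!length(checks)) checks <- horizon - 50
    pauses <- pmin(rtruncnorm(length(checks), cfg$pause_mean, cfg$pause_sd,
                              lower = 4), 40)
    check_ends <- checks + 0.6 * pauses
    shocked <- stats::runif(length(checks)) < cfg$p_defib_per_check
    shocks <- (checks + 0.85 * pauses)[shocked]

    # compressor changes on their own drifted two-minute cycle
    changes <- numeric(0)
    t <- arrival
    repeat {
      t <- t + 120 + rtruncnorm(1, cfg$change_drift_mean, cfg$change_drift_sd)
      if (t > horizon - 5) break
      changes <- c(changes, t)
    }

    # adrenaline doses
    doses <- numeric(0)
    t <- arrival + rtruncnorm(1, cfg$first_dose_mean, cfg$first_dose_sd, lower = 30)
    while (t <= horizon - 5) {
      doses <- c(doses, t)
      t <- t + rtruncnorm(1, cfg$adrenaline_interval_mean,
                          cfg$adrenaline_interval_sd, lower = 60)
    }

    amio <- if (length(shocks) >= 3 &&
                stats::runif(1) < cfg$amiodarone_compliance)
      shocks[3] + stats::runif(1, 10, 50) else numeric(0)
    amio <- amio[amio <= horizon]

    # compressions: start after the initial delay, pause around each check
    comp_start <- min(arrival + rtruncnorm(1, cfg$initial_delay_mean,
                                           cfg$initial_delay_sd, lower = 2),
                      checks[1] - 1)
    starts <- c(comp_start, checks + pauses)
    stops <- c(checks, horizon)
    keep <- starts < stops  # guard against a pause extending past the horizon
    starts <- starts[keep]; stops <- stops[keep]

    ev <- rbind(
      data.frame(kind = "COMPRESSIONS_START", timestamp = starts),
      data.frame(kind = "COMPRESSIONS_STOP", timestamp = stops),
      data.frame(kind = "RHYTHM_CHECK_START", timestamp = checks),
      data.frame(kind = "RHYTHM_CHECK_END", timestamp = check_ends),
      data.frame(kind = "DEFIBRILLATION", timestamp = shocks),
      data.frame(kind = "COMPRESSOR_CHANGE", timestamp = changes),
      data.frame(kind = "ADRENALINE", timestamp = doses),
      if (length(amio)) data.frame(kind = "AMIODARONE", timestamp = amio),
      if (!is.na(cfg$rosc_time) && cfg$rosc_time <= scen_end)
        data.frame(kind = "ROSC", timestamp = cfg$rosc_time))
    ev <- ev[ev$timestamp <= scen_end, ]

    log <- event_log(team_id = team_id, group = cfg$group,
                     arrival_time = arrival, scenario_end = scen_end,
                     events = ev, rosc_time = cfg$rosc_time)

    series <- if (stats::runif(1) < cfg$p_missing_compression) {
      compression_series(team_id, available = FALSE)
    } else {
      bounds <- sort(unique(c(arrival, checks, horizon)))
      bounds <- bounds[bounds <= horizon]
      if (bounds[length(bounds)] < horizon) bounds <- c(bounds, horizon)
      np <- length(bounds) - 1
      compression_series(team_id, data.frame(
        period_start = bounds[-length(bounds)],
        period_end = bounds[-1],
        mean_depth = pmin(pmax(stats::rnorm(np, cfg$depth_mean, cfg$depth_sd),
                               0.5), 9.5),
        mean_rate = pmin(pmax(stats::rnorm(np, cfg$rate_mean, cfg$rate_sd),
                              40), 199)))
    }

    interactions <- NULL
    if (cfg$group == "CA_APP") {
      presses <- rbind(
        data.frame(t = check_ends, button = "RHYTHM_CHECK"),
        data.frame(t = shocks + 1, button = "DEFIB"),
        data.frame(t = doses + 2, button = "ADRENALINE"),
        if (length(amio)) data.frame(t = amio + 2, button = "AMIODARONE"))
      n_extra <- stats::rpois(1, 0.7 * len / 60)
      if (n_extra > 0)
        presses <- rbind(presses, data.frame(
          t = arrival + stats::runif(n_extra, 0, len),
          button = sample(c("HS_TS_EXPAND", "OTHER_INTERVENTION_1",
                            "OTHER_INTERVENTION_2", "OTHER_INTERVENTION_3"),
                          n_extra, replace = TRUE)))
      presses <- presses[order(presses$t), ]
      state <- aid_init()
      clock <- arrival
      recs <- vector("list", nrow(presses))
      for (i in seq_len(nrow(presses))) {
        state <- aid_advance(state, presses$t[i] - clock)
        clock <- presses$t[i]
        out <- aid_press(state, presses$button[i], timestamp = clock - arrival)
        state <- out$state
        recs[[i]] <- out$record
      }
      interactions <- do.call(rbind, recs)
    }
    list(log = log, series = series, interactions = interactions)
  })
}

#' Simulate a full cohort and write it in the event-log dialect
#'
#' Runs [simulate_team_log()] for `cfg$n_teams` teams (per-team seeds derived
#' from the master seed) and, if `dir` is given, writes one event file and
#' optional compression file per team plus a manifest.
#'
#' @param cfg a [behavior_config()].
#' @param dir output directory (`NULL` to keep the cohort in memory only).
#' @param prefix team-id prefix.
#' @return list with `manifest` (data frame), `logs`, `series`,
#'   `interactions` (named lists) and, when written, `manifest_path`.
#' @export
simulate_cohort <- function(cfg, dir = NULL, prefix = cfg$group) {
  teams <- lapply(seq_len(cfg$n_teams), function(i) {
    simulate_team_log(cfg, derive_seed(cfg$seed, i),
                      team_id = sprintf("%s_%03d", prefix, i))
  })
  ids <- vapply(teams, function(t) t$log$team_id, "")
  logs <- stats::setNames(lapply(teams, `[[`, "log"), ids)
  series <- stats::setNames(lapply(teams, `[[`, "series"), ids)
  inter <- stats::setNames(lapply(teams, `[[`, "interactions"), ids)

  man <- data.frame(
    team_id = ids,
    group = cfg$group,
    arrival_time_s = vapply(logs, `[[`, 0, "arrival_time"),
    scenario_end_s = vapply(logs, `[[`, 0, "scenario_end"),
    event_file = paste0(ids, "_events.csv"),
    compression_file = ifelse(vapply(series, `[[`, TRUE, "available"),
                              paste0(ids, "_compressions.csv"), NA_character_),
    excluded = FALSE,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  rownames(man) <- NULL

  out <- list(manifest = man, logs = logs, series = series,
              interactions = inter)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(ids)) {
      write_event_log(logs[[i]], file.path(dir, man$event_file[i]))
      if (!is.na(man$compression_file[i]))
        write_compression_series(series[[i]],
                                 file.path(dir, man$compression_file[i]))
      if (!is.null(inter[[i]]))
        write_interaction_log(inter[[i]],
                              file.path(dir, paste0(ids[i], "_interactions.csv")))
    }
    out$manifest_path <- file.path(dir, paste0(prefix, "_manifest.csv"))
    write_manifest(man, out$manifest_path)
  }
  out
}
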