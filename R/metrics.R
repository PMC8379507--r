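#' ALS algorithm timing targets
#'
#' Configuration for the guideline targets against which deviations and
#' expected action counts are computed: the two-minute rhythm-check /
#' compressor-change cycle, the 3--5 minute adrenaline window, and the margin
#' fraction used by the scoring rubric.
#'
#' @param cycle_target target interval between rhythm checks and compressor
#'   changes, seconds (default 120).
#' @param adrenaline_window length-2 numeric, lower and upper bound of the
#'   inter-dose window in seconds (default `c(180, 300)`).
#' @param margin margin fraction for rubric bands (default 0.15).
#' @return a list of class `algorithm_targets`.
#' @export
algorithm_targets <- function(cycle_target = 120,
                              adrenaline_window = c(180, 300),
                              margin = 0.15) {
  if (cycle_target <= 0) stop_arg("cycle_target must be positive")
  if (length(adrenaline_window) != 2 ||
      adrenaline_window[1] >= adrenaline_window[2])
    stop_arg("adrenaline_window must be (low, high) with low < high")
  if (margin <= 0) stop_arg("margin must be positive")
  structure(list(cycle_target = cycle_target,
                 adrenaline_window = as.numeric(adrenaline_window),
                 margin = margin),
            class = "algorithm_targets")
}

# [start, stop) compression segments clipped to the arrest window; an
# unmatched trailing start means compressions ran until the window end
compression_segments <- function(log, clip_to = NULL) {
  ev <- log$events
  comp <- ev[ev$kind %in% c("COMPRESSIONS_START", "COMPRESSIONS_STOP"), ,
             drop = FALSE]
  starts <- comp$timestamp[comp$kind == "COMPRESSIONS_START"]
  stops <- comp$timestamp[comp$kind == "COMPRESSIONS_STOP"]
  end_default <- if (is.null(clip_to)) log$scenario_end else clip_to[2]
  if (length(stops) < length(starts)) stops <- c(stops, end_default)
  seg <- data.frame(start = starts, stop = stops)
  if (!is.null(clip_to)) {
    seg$start <- pmax(seg$start, clip_to[1])
    seg$stop <- pmin(seg$stop, clip_to[2])
    seg <- seg[seg$stop > seg$start, , drop = FALSE]
  }
  seg
}

arrest_window <- function(log) {
  end <- if (!is.na(log$rosc_time)) min(log$rosc_time, log$scenario_end)
         else log$scenario_end
  c(log$arrival_time, end)
}

#' No-flow fraction of a resuscitation
#'
#' The no-flow fraction is the percentage of the cardiac-arrest interval
#' during which no chest compressions were delivered. The arrest interval
#' runs from team arrival to ROSC or scenario end, whichever is earlier;
#' compression segments are half-open `[start, stop)` and clipped to that
#' window.
#'
#' @param log a valid `cpr_event_log`.
#' @return no-flow fraction in percent, in `[0, 100]`.
#' @export
no_flow_fraction <- function(log) {
  win <- arrest_window(log)
  arrest <- win[2] - win[1]
  if (arrest <= 0) stop_arg("arrest interval has non-positive length")
  seg <- compression_segments(log, clip_to = win)
  flow <- sum(seg$stop - seg$start)
  100 * (arrest - flow) / arrest
}

#' Time from arrival to the first event of a kind
#'
#' @param log a valid `cpr_event_log`.
#' @param kind one of [EVENT_KINDS].
#' @return seconds from `arrival_time` to the first event of `kind`, or
#'   `NA` if the event never occurred (e.g. a team that never defibrillated).
#' @export
time_to_first <- function(log, kind) {
  kind <- match.arg(kind, EVENT_KINDS)
  ts <- log$events$timestamp[log$events$kind == kind]
  if (!length(ts)) return(NA_real_)
  min(ts) - log$arrival_time
}

#' Mean delay of a cyclic action beyond its target interval
#'
#' For actions the ALS algorithm schedules on a fixed cycle (rhythm checks,
#' compressor changes): each interval is compared with the target; an
#' interval at or under the target is guideline-conform with delay zero,
#' otherwise the delay in seconds is `interval - target`. The first interval
#' is measured from `origin` (normally team arrival) to the first event,
#' subsequent intervals between consecutive events.
#'
#' @param timestamps ordered event times in seconds.
#' @param target target interval in seconds.
#' @param origin anchor for the first interval.
#' @return list with `mean_dev` (mean of `max(0, interval - target)`; `NA`
#'   when there are no events) and `n_events`.
#' @export
interval_deviation <- function(timestamps, target, origin = 0) {
  if (!length(timestamps)) return(list(mean_dev = NA_real_, n_events = 0L))
  if (is.unsorted(timestamps)) stop_arg("`timestamps` must be ordered")
  intervals <- diff(c(origin, timestamps))
  list(mean_dev = mean(pmax(0, intervals - target)),
       n_events = length(timestamps))
}

#' Mean deviation of adrenaline dosing from the 3--5 minute window
#'
#' Repeat dosing is judged on the interval between consecutive doses; the
#' first dose carries no deviation. An interval shorter than the window is
#' an early deviation (`low - interval` seconds), longer a late deviation
#' (`interval - high`), inside the window a conform administration with
#' deviation zero; the deviations are averaged over the intervals.
#'
#' @param timestamps ordered dose times in seconds.
#' @param window length-2 numeric `(low, high)` in seconds, default
#'   `c(180, 300)`.
#' @return list with `mean_dev` (0 when fewer than two doses) and `n_doses`.
#' @export
adrenaline_deviation <- function(timestamps, window = c(180, 300)) {
  n <- length(timestamps)
  if (n < 2) return(list(mean_dev = 0, n_doses = n))
  if (is.unsorted(timestamps)) stop_arg("`timestamps` must be ordered")
  d <- diff(timestamps)
  dev <- pmax(0, window[1] - d) + pmax(0, d - window[2])
  list(mean_dev = mean(dev), n_doses = n)
}

#' Expected number of cyclic actions for a scenario length
#'
#' Longer scenarios require more rhythm checks, compressor changes and
#' adrenaline doses. Rhythm checks and compressor changes are expected once
#' per two-minute cycle; adrenaline once per 240 s (the midpoint of the
#' 3--5 minute window). The rule is a configurable convention, isolated in
#' [algorithm_targets()] so an alternative table can be dropped in.
#'
#' @param scenario_length scenario length in seconds (positive).
#' @param kind `"rhythm_check"`, `"compressor_change"` or `"adrenaline"`.
#' @param targets an [algorithm_targets()] object.
#' @return expected count (non-negative integer).
#' @export
expected_count <- function(scenario_length,
                           kind = c("rhythm_check", "compressor_change",
                                    "adrenaline"),
                           targets = algorithm_targets()) {
  kind <- match.arg(kind)
  if (!is.numeric(scenario_length) || scenario_length <= 0)
    stop_arg("scenario_length must be positive")
  period <- switch(kind,
                   rhythm_check = ,
                   compressor_change = targets$cycle_target,
                   adrenaline = mean(targets$adrenaline_window))
  as.integer(floor(scenario_length / period))
}

#' Classify amiodarone administration
#'
#' @param log a valid `cpr_event_log`.
#' @return `"NONE"` if amiodarone was never given; `"AFTER_THIRD_SHOCK"` if
#'   the first dose fell after the third and before the fourth
#'   defibrillation (the guideline-conform indication); `"GIVEN"` for any
#'   other timing.
#' @export
amiodarone_class <- function(log) {
  ev <- log$events
  amio <- ev$timestamp[ev$kind == "AMIODARONE"]
  if (!length(amio)) return("NONE")
  shocks <- sort(ev$timestamp[ev$kind == "DEFIBRILLATION"])
  t <- min(amio)
  if (length(shocks) >= 3 && t > shocks[3] &&
      (length(shocks) < 4 || t < shocks[4])) "AFTER_THIRD_SHOCK" else "GIVEN"
}

#' Duration-weighted average compression depth and rate
#'
#' @param series a `cpr_compression_series`.
#' @return list with `depth` (cm) and `rate` (per minute), both `NA` when the
#'   series is unavailable or empty.
#' @export
average_compression_quality <- function(series) {
  if (!series$available || nrow(series$samples) == 0)
    return(list(depth = NA_real_, rate = NA_real_))
  s <- series$samples
  w <- s$period_end - s$period_start
  list(depth = sum(w * s$mean_depth) / sum(w),
       rate = sum(w * s$mean_rate) / sum(w))
}

#' Compute the twelve CPR performance variables for one team
#'
#' Populates every performance variable from the event log and, when
#' available, the compression-quality series: no-flow fraction, average
#' compression depth and rate, times to first rhythm analysis and first
#' shock, observed counts and cycle deviations for compressor changes,
#' adrenaline and rhythm checks, and the amiodarone timing class. Rhythm
#' cycle deviations use rhythm-check start times (the cycle is defined by
#' when compressions pause for analysis). The scenario length reported (and
#' used for expected counts) is `scenario_end - arrival_time`, so results
#' are invariant to translating the whole record in time.
#'
#' @param log a valid `cpr_event_log`.
#' @param series optional `cpr_compression_series`; `NULL` means unavailable.
#' @param targets an [algorithm_targets()] object.
#' @return object of class `cpr_performance` (a named list of the twelve
#'   variables plus `team_id`, `group` and `scenario_length`).
#' @export
compute_performance <- function(log, series = NULL,
                                targets = algorithm_targets()) {
  if (is.null(series)) series <- compression_series(log$team_id, available = FALSE)
  ev <- log$events
  ts_of <- function(kind) sort(ev$timestamp[ev$kind == kind])

  rhythm <- ts_of("RHYTHM_CHECK_START")
  changes <- ts_of("COMPRESSOR_CHANGE")
  adren <- ts_of("ADRENALINE")

  dev_r <- interval_deviation(rhythm, targets$cycle_target, log$arrival_time)
  dev_c <- interval_deviation(changes, targets$cycle_target, log$arrival_time)
  dev_a <- adrenaline_deviation(adren, targets$adrenaline_window)
  qual <- average_compression_quality(series)

  structure(list(
    team_id = log$team_id,
    group = log$group,
    no_flow_fraction = no_flow_fraction(log),
    avg_depth = qual$depth,
    avg_rate = qual$rate,
    t_first_rhythm = time_to_first(log, "RHYTHM_CHECK_START"),
    t_first_shock = time_to_first(log, "DEFIBRILLATION"),
    n_compressor_changes = dev_c$n_events,
    dev_compressor_change = if (is.na(dev_c$mean_dev)) 0 else dev_c$mean_dev,
    n_adrenaline = dev_a$n_doses,
    dev_adrenaline = dev_a$mean_dev,
    n_rhythm_checks = dev_r$n_events,
    dev_rhythm = if (is.na(dev_r$mean_dev)) 0 else dev_r$mean_dev,
    amiodarone_class = amiodarone_class(log),
    scenario_length = log$scenario_end - log$arrival_time
  ), class = "cpr_performance")
}

#' Performance variables of several teams as a data frame
#'
#' @param perfs list of `cpr_performance` objects.
#' @return one row per team, columns as in [compute_performance()].
#' @export
performance_table <- function(perfs) {
  do.call(rbind, lapply(perfs, function(p)
    data.frame(unclass(p), stringsAsFactors = FALSE)))
}
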