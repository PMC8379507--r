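#' Buttons exposed by the cognitive-aid application
#'
#' Documentation buttons of the tablet aid: rhythm check, defibrillation,
#' adrenaline and amiodarone documentation, the compressions/ROSC toggle,
#' three free-assignment intervention buttons, and expanding the reversible
#' causes (Hs and Ts) panel.
#'
#' @export
AID_BUTTONS <- c("RHYTHM_CHECK", "DEFIB", "ADRENALINE", "AMIODARONE",
                 "HDM_ROSC_TOGGLE", "OTHER_INTERVENTION_1",
                 "OTHER_INTERVENTION_2", "OTHER_INTERVENTION_3", "HS_TS_EXPAND")

#' Alert thresholds of the aid engine
#'
#' The rhythm-check timer escalates at 01:40 (prepare; orange) and 02:00
#' (due; red), matching the two-minute ALS cycle; the compressor-change icon
#' appears together with the prepare alert. The adrenaline timer turns to
#' "consider" at the start of the 3--5 minute dosing window. All values are
#' seconds and configurable because the visible app prints only the two
#' rhythm thresholds.
#'
#' @param rhythm_prepare seconds on the rhythm timer at which the prepare
#'   alert (and the compressor-change prompt) appears; default 100.
#' @param rhythm_due seconds at which the rhythm check becomes due; default 120.
#' @param adrenaline_consider seconds since the last dose at which the next
#'   administration should be considered; default 180.
#' @return a list of thresholds used by [aid_init()].
#' @export
aid_config <- function(rhythm_prepare = 100, rhythm_due = 120,
                       adrenaline_consider = 180) {
  if (rhythm_prepare <= 0 || rhythm_due <= rhythm_prepare)
    stop_arg("need 0 < rhythm_prepare < rhythm_due")
  if (adrenaline_consider <= 0) stop_arg("adrenaline_consider must be positive")
  list(rhythm_prepare = rhythm_prepare, rhythm_due = rhythm_due,
       adrenaline_consider = adrenaline_consider)
}

recompute_alerts <- function(state) {
  cfg <- state$config
  state$rhythm_alert <-
    if (state$t_rhythm >= cfg$rhythm_due) "DUE"
    else if (state$t_rhythm >= cfg$rhythm_prepare) "PREPARE"
    else "NONE"
  state$compressor_change_prompt <- state$t_rhythm >= cfg$rhythm_prepare
  state$adrenaline_alert <-
    if (!is.na(state$t_adrenaline) &&
        adrenaline_alert_rule(state$t_adrenaline, cfg$adrenaline_consider) == "CONSIDER")
      "CONSIDER" else "NONE"
  # amiodarone_prompt latches until AMIODARONE is documented
  state
}

#' Initialise the cognitive-aid state
#'
#' All timers start at zero (the adrenaline timer is absent until the first
#' dose is documented), all counters at zero, all alerts off, compressions
#' mode `CPR`. The engine has no real-time clock: it is advanced explicitly
#' with [aid_advance()], which keeps replays deterministic.
#'
#' @param config thresholds from [aid_config()].
#' @return an object of class `aid_state`.
#' @export
aid_init <- function(config = aid_config()) {
  state <- structure(
    list(t_arrival = 0, t_rhythm = 0, t_adrenaline = NA_real_,
         defib_count = 0L, compressions_mode = "CPR",
         rhythm_alert = "NONE", compressor_change_prompt = FALSE,
         adrenaline_alert = "NONE", amiodarone_prompt = FALSE,
         config = config),
    class = "aid_state")
  recompute_alerts(state)
}

#' Advance the aid engine's timers
#'
#' Pure function: all running timers increase by `dt` and the alert fields
#' are recomputed from the new timer values (the amiodarone prompt latches
#' and is unaffected by time).
#'
#' @param state an `aid_state`.
#' @param dt non-negative seconds to advance.
#' @return the new `aid_state`.
#' @export
aid_advance <- function(state, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || is.na(dt) || dt < 0)
    stop_arg("`dt` must be a single non-negative number of seconds")
  state$t_arrival <- state$t_arrival + dt
  state$t_rhythm <- state$t_rhythm + dt
  if (!is.na(state$t_adrenaline)) state$t_adrenaline <- state$t_adrenaline + dt
  recompute_alerts(state)
}

#' Press a button of the cognitive aid
#'
#' Every press is legal at any time, mirroring the app. Documentation
#' presses reset the corresponding timer: `RHYTHM_CHECK` zeroes the rhythm
#' timer (clearing its alerts and the compressor-change prompt),
#' `ADRENALINE` starts/zeroes the adrenaline timer, `DEFIB` increments the
#' shock counter and raises the amiodarone prompt whenever the count reaches
#' a positive multiple of three, `AMIODARONE` clears that prompt, and
#' `HDM_ROSC_TOGGLE` flips between compressions (`CPR`) and `ROSC` mode.
#'
#' @param state an `aid_state`.
#' @param button one of [AID_BUTTONS].
#' @param timestamp seconds since arrival, recorded in the interaction log.
#' @return list with elements `state` (new `aid_state`) and `record`
#'   (one-row data frame `timestamp`, `button`).
#' @export
aid_press <- function(state, button, timestamp = state$t_arrival) {
  button <- match.arg(button, AID_BUTTONS)
  if (button == "RHYTHM_CHECK") {
    state$t_rhythm <- 0
  } else if (button == "ADRENALINE") {
    state$t_adrenaline <- 0
  } else if (button == "DEFIB") {
    state$defib_count <- state$defib_count + 1L
    if (state$defib_count %% 3L == 0L) state$amiodarone_prompt <- TRUE
  } else if (button == "AMIODARONE") {
    state$amiodarone_prompt <- FALSE
  } else if (button == "HDM_ROSC_TOGGLE") {
    state$compressions_mode <- if (state$compressions_mode == "CPR") "ROSC" else "CPR"
  }
  state <- recompute_alerts(state)
  list(state = state,
       record = data.frame(timestamp = as.numeric(timestamp), button = button,
                           stringsAsFactors = FALSE))
}

#' Adrenaline alert rule
#'
#' The next administration should be considered once the time since the last
#' documented dose reaches the start of the 3--5 minute dosing window.
#'
#' @param t_adrenaline seconds since the last documented dose.
#' @param consider_at threshold in seconds (default 180).
#' @return `"CONSIDER"` or `"NONE"`.
#' @export
adrenaline_alert_rule <- function(t_adrenaline, consider_at = 180) {
  if (is.na(t_adrenaline)) stop_arg("adrenaline timer is absent (no dose documented)")
  if (t_adrenaline >= consider_at) "CONSIDER" else "NONE"
}

#' Physical interactions with the aid per minute
#'
#' @param records data frame of interaction records (`timestamp`, `button`)
#'   as produced by [aid_press()] / [simulate_team_log()].
#' @param duration scenario duration in seconds (must be positive).
#' @return interactions per minute.
#' @export
interactions_per_minute <- function(records, duration) {
  if (!is.numeric(duration) || length(duration) != 1 || is.na(duration) ||
      duration <= 0)
    stop_arg("`duration` must be a single positive number of seconds")
  n <- if (is.null(records)) 0L else nrow(records)
  n * 60 / duration
}

#' Write / read an aid interaction log
#'
#' Delimited export with columns `timestamp_s`, `button`.
#'
#' @param records interaction records data frame.
#' @param path file path.
#' @return `write_interaction_log()` returns `path` invisibly;
#'   `read_interaction_log()` returns the records.
#' @export
write_interaction_log <- function(records, path) {
  utils::write.csv(
    data.frame(timestamp_s = records$timestamp, button = records$button),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_interaction_log
#' @export
read_interaction_log <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(timestamp = tab$timestamp_s, button = tab$button,
             stringsAsFactors = FALSE)
}
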