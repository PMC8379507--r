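#' Recognised event kinds in a resuscitation event log
#'
#' Compression start/stop events delimit flow (hands-on) segments; rhythm
#' checks are coded as start/end intervals because compressions pause for the
#' analysis; defibrillation, drug administrations, compressor changes and
#' ROSC are instantaneous point events.
#'
#' @export
EVENT_KINDS <- c(
  "COMPRESSIONS_START", "COMPRESSIONS_STOP",
  "RHYTHM_CHECK_START", "RHYTHM_CHECK_END",
  "DEFIBRILLATION", "ADRENALINE", "AMIODARONE",
  "COMPRESSOR_CHANGE", "ROSC"
)

#' Study arms
#' @export
GROUPS <- c("CA_APP", "NO_APP")

#' Construct a resuscitation event log
#'
#' An event log is the atomic input of the pipeline: one team's coded
#' scenario, with all timestamps in seconds from scenario start (t = 0 is
#' scenario start, not team arrival; metrics subtract `arrival_time`
#' explicitly).
#'
#' @param team_id opaque team identifier (character scalar).
#' @param group study arm, one of `"CA_APP"` or `"NO_APP"`.
#' @param arrival_time seconds from scenario start at which the team reached
#'   the patient.
#' @param scenario_end scenario length in seconds from scenario start.
#' @param events data frame with columns `kind` (see [EVENT_KINDS]) and
#'   `timestamp` (seconds). Rows are sorted by timestamp on construction.
#' @param excluded logical flag: team excluded from scoring by the analyst.
#' @param exclusion_reason free-text reason (NA if not excluded).
#' @param rosc_time optional time of return of spontaneous circulation in
#'   seconds; `NA` if the scenario ended without ROSC. If omitted it is taken
#'   from the first `ROSC` event, when present.
#' @param validate if `TRUE` (default) an invalid log raises an error naming
#'   the violated rule; use [validate_log()] for non-throwing validation.
#'
#' @return an object of class `cpr_event_log`.
#' @seealso [read_event_log()], [write_event_log()], [validate_log()]
#' @export
event_log <- function(team_id, group, arrival_time, scenario_end,
                      events, excluded = FALSE, exclusion_reason = NA_character_,
                      rosc_time = NULL, validate = TRUE) {
  if (!is.data.frame(events) || !all(c("kind", "timestamp") %in% names(events)))
    stop_arg("`events` must be a data frame with columns 'kind' and 'timestamp'")
  events <- data.frame(kind = as.character(events$kind),
                       timestamp = as.numeric(events$timestamp),
                       stringsAsFactors = FALSE)
  events <- events[order(events$timestamp), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(rosc_time)) {
    ro <- events$timestamp[events$kind == "ROSC"]
    rosc_time <- if (length(ro)) ro[1] else NA_real_
  }
  log <- structure(
    list(team_id = as.character(team_id),
         group = match.arg(group, GROUPS),
         arrival_time = as.numeric(arrival_time),
         scenario_end = as.numeric(scenario_end),
         events = events,
         excluded = isTRUE(excluded),
         exclusion_reason = as.character(exclusion_reason),
         rosc_time = as.numeric(rosc_time)),
    class = "cpr_event_log")
  if (validate) {
    v <- validate_log(log)
    if (nrow(v) > 0)
      stop_arg("invalid event log '%s': %s", log$team_id,
               paste(unique(v$rule), collapse = ", "))
  }
  log
}

#' @export
print.cpr_event_log <- function(x, ...) {
  cat(sprintf("<cpr_event_log> team %s (%s): %d events, arrival %.1f s, end %.1f s%s%s\n",
              x$team_id, x$group, nrow(x$events), x$arrival_time, x$scenario_end,
              if (!is.na(x$rosc_time)) sprintf(", ROSC %.1f s", x$rosc_time) else "",
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' Validate an event log against its structural invariants
#'
#' A reporting operation: it never raises on a structurally complete log, it
#' returns one row per violation. Rules checked:
#' \describe{
#'   \item{kind}{every event kind is recognised;}
#'   \item{sorted}{events ordered by timestamp;}
#'   \item{bounds}{all timestamps within `[0, scenario_end]`;}
#'   \item{alternation}{compression start/stop events strictly alternate,
#'     beginning with a start (a trailing unmatched start means compressions
#'     were ongoing at scenario end and is legal);}
#'   \item{pairing}{every rhythm-check end follows its start, with no nesting;}
#'   \item{arrival}{`arrival_time` does not exceed the first clinical event;}
#'   \item{scenario_end}{`scenario_end > arrival_time`.}
#' }
#'
#' @param log a `cpr_event_log`.
#' @return data frame with columns `rule`, `timestamp`, `message`; zero rows
#'   iff the log is valid.
#' @export
validate_log <- function(log) {
  viol <- function(rule, timestamp, message)
    data.frame(rule = rule, timestamp = timestamp, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  ev <- log$events

  bad_kind <- !(ev$kind %in% EVENT_KINDS)
  if (any(bad_kind))
    out[[length(out) + 1]] <- viol("kind", ev$timestamp[bad_kind],
                                   paste("unknown event kind:", ev$kind[bad_kind]))
  if (is.unsorted(ev$timestamp))
    out[[length(out) + 1]] <- viol("sorted", NA_real_, "events not sorted by timestamp")
  oob <- ev$timestamp < 0 | ev$timestamp > log$scenario_end
  oob[is.na(oob)] <- TRUE
  if (any(oob))
    out[[length(out) + 1]] <- viol("bounds", ev$timestamp[oob],
                                   "timestamp outside [0, scenario_end]")

  comp <- ev[ev$kind %in% c("COMPRESSIONS_START", "COMPRESSIONS_STOP"), , drop = FALSE]
  if (nrow(comp) > 0) {
    expected <- rep(c("COMPRESSIONS_START", "COMPRESSIONS_STOP"),
                    length.out = nrow(comp))
    bad <- comp$kind != expected
    if (any(bad))
      out[[length(out) + 1]] <- viol("alternation", comp$timestamp[which(bad)[1]],
                                     "compression start/stop events do not alternate starting with a start")
  }

  rc <- ev[ev$kind %in% c("RHYTHM_CHECK_START", "RHYTHM_CHECK_END"), , drop = FALSE]
  if (nrow(rc) > 0) {
    depth <- cumsum(ifelse(rc$kind == "RHYTHM_CHECK_START", 1L, -1L))
    if (any(depth < 0 | depth > 1) || depth[length(depth)] > 1) {
      first_bad <- which(depth < 0 | depth > 1)[1]
      out[[length(out) + 1]] <- viol("pairing",
                                     rc$timestamp[if (is.na(first_bad)) nrow(rc) else first_bad],
                                     "rhythm-check start/end events are not properly paired")
    }
  }

  if (nrow(ev) > 0 && min(ev$timestamp, na.rm = TRUE) < log$arrival_time)
    out[[length(out) + 1]] <- viol("arrival", min(ev$timestamp, na.rm = TRUE),
                                   "clinical event precedes arrival_time")
  if (!is.na(log$scenario_end) && !is.na(log$arrival_time) &&
      log$scenario_end <= log$arrival_time)
    out[[length(out) + 1]] <- viol("scenario_end", log$scenario_end,
                                   "scenario_end must exceed arrival_time")

  if (length(out) == 0)
    return(data.frame(rule = character(), timestamp = numeric(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# header fields serialised as '#key value' comment lines atop the event table
.log_header_fields <- c("team_id", "group", "arrival_time_s", "scenario_end_s",
                        "rosc_time_s", "excluded", "exclusion_reason")

#' Write an event log to a delimited file
#'
#' The file carries the team-level metadata as `#key value` comment lines
#' followed by a `kind,timestamp_s` table, so a single file fully round-trips
#' one team's record. Optional fields (`rosc_time`, `exclusion_reason`) are
#' written as the explicit marker `NA`.
#'
#' @param log a valid `cpr_event_log`.
#' @param path output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  hdr <- c(
    team_id = log$team_id,
    group = log$group,
    arrival_time_s = fmt17(log$arrival_time),
    scenario_end_s = fmt17(log$scenario_end),
    rosc_time_s = fmt17(log$rosc_time),
    excluded = if (log$excluded) "TRUE" else "FALSE",
    exclusion_reason = if (is.na(log$exclusion_reason)) "NA" else log$exclusion_reason
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", names(hdr), " ", unname(hdr)), con)
  writeLines(paste("kind", "timestamp_s", sep = sep), con)
  if (nrow(log$events) > 0)
    writeLines(paste(log$events$kind, fmt17(log$events$timestamp),
                     sep = sep), con)
  invisible(path)
}

#' Read an event log from a delimited file
#'
#' Inverse of [write_event_log()]: `read_event_log(write_event_log(log, p), p)`
#' reproduces `log` field for field.
#'
#' @param path file written by [write_event_log()] (or hand-authored in the
#'   same dialect).
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return a validated `cpr_event_log`.
#' @export
read_event_log <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (!file.exists(path)) stop_arg("event-log file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#(\\S+)\\s*(.*)$", h))[[1]]
    if (length(m) == 3) hdr[[m[2]]] <- m[3]
  }
  missing_hdr <- setdiff(.log_header_fields, names(hdr))
  if (length(missing_hdr))
    stop_arg("parse error in %s: missing header field(s) %s", path,
             paste(missing_hdr, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0 || !identical(strsplit(body[1], sep, fixed = TRUE)[[1]],
                                      c("kind", "timestamp_s")))
    stop_arg("parse error in %s: expected header row 'kind%stimestamp_s'", path, sep)
  ev <- if (length(body) > 1) {
    parts <- strsplit(body[-1], sep, fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad))
      stop_arg("parse error in %s at data line %d: expected 2 fields", path, bad[1])
    ts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(ts)) {
      bad <- which(is.na(ts))[1]
      stop_arg("parse error in %s at data line %d: non-numeric timestamp", path, bad)
    }
    data.frame(kind = vapply(parts, `[`, "", 1L), timestamp = ts,
               stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(), timestamp = numeric(), stringsAsFactors = FALSE)
  }
  num_or_na <- function(x) if (identical(x, "NA")) NA_real_ else as.numeric(x)
  event_log(
    team_id = hdr$team_id,
    group = hdr$group,
    arrival_time = as.numeric(hdr$arrival_time_s),
    scenario_end = as.numeric(hdr$scenario_end_s),
    events = ev,
    excluded = identical(hdr$excluded, "TRUE"),
    exclusion_reason = if (identical(hdr$exclusion_reason, "NA")) NA_character_
                       else hdr$exclusion_reason,
    rosc_time = num_or_na(hdr$rosc_time_s)
  )
}

#' Construct a compression-quality series
#'
#' Per-period averages of chest-compression depth and rate, emulating the
#' export of manikin simulator software. `available = FALSE` models the
#' technical failures that leave a team without compression data (the team is
#' then scored on the remaining ten variables).
#'
#' @param team_id team identifier.
#' @param samples data frame with columns `period_start`, `period_end`
#'   (seconds), `mean_depth` (cm, in (0, 10)) and `mean_rate` (per minute,
#'   in (0, 200)); periods must not overlap.
#' @param available logical; `FALSE` marks the series as missing.
#' @return an object of class `cpr_compression_series`.
#' @export
compression_series <- function(team_id, samples = NULL, available = TRUE) {
  if (is.null(samples))
    samples <- data.frame(period_start = numeric(), period_end = numeric(),
                          mean_depth = numeric(), mean_rate = numeric())
  need <- c("period_start", "period_end", "mean_depth", "mean_rate")
  if (!all(need %in% names(samples)))
    stop_arg("`samples` must have columns %s", paste(need, collapse = ", "))
  samples <- samples[order(samples$period_start), need, drop = FALSE]
  rownames(samples) <- NULL
  if (available && nrow(samples) > 0) {
    if (any(samples$mean_depth <= 0 | samples$mean_depth >= 10))
      stop_arg("compression depth must lie in (0, 10) cm")
    if (any(samples$mean_rate <= 0 | samples$mean_rate >= 200))
      stop_arg("compression rate must lie in (0, 200) per minute")
    if (any(samples$period_end <= samples$period_start))
      stop_arg("each period must have period_end > period_start")
    if (nrow(samples) > 1 &&
        any(samples$period_start[-1] < samples$period_end[-nrow(samples)] - 1e-9))
      stop_arg("compression periods must not overlap")
  }
  structure(list(team_id = as.character(team_id), samples = samples,
                 available = isTRUE(available)),
            class = "cpr_compression_series")
}

#' Write / read a compression-quality series
#'
#' Delimited format with columns `period_start_s`, `period_end_s`,
#' `mean_depth_cm`, `mean_rate_per_min` and a `#team_id` comment header.
#'
#' @param series a `cpr_compression_series`.
#' @param path file path.
#' @return `write_compression_series()` returns `path` invisibly;
#'   `read_compression_series()` returns the series.
#' @export
write_compression_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#team_id ", series$team_id), con)
  writeLines(paste0("#available ", if (series$available) "TRUE" else "FALSE"), con)
  tab <- stats::setNames(series$samples,
                         c("period_start_s", "period_end_s",
                           "mean_depth_cm", "mean_rate_per_min"))
  tab[] <- lapply(tab, fmt17)
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_compression_series
#' @export
read_compression_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    h <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (!length(h)) stop_arg("parse error in %s: missing #%s header", path, key)
    sub(paste0("^#", key, " "), "", h[1])
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  names(tab) <- sub("_s$|_cm$|_per_min$", "", names(tab))
  compression_series(team_id = get("team_id"), samples = tab,
                     available = identical(get("available"), "TRUE"))
}

#' Write / read a cohort manifest
#'
#' A manifest lists one team per row: identifier, study arm, arrival and
#' scenario-end times, the per-team event and (optional) compression files,
#' and the analyst's exclusion flag. Paths are stored relative to the
#' manifest's directory.
#'
#' @param manifest data frame with columns `team_id`, `group`,
#'   `arrival_time_s`, `scenario_end_s`, `event_file`, `compression_file`
#'   (NA when absent), `excluded`, `exclusion_reason`.
#' @param path manifest file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("team_id", "group", "arrival_time_s", "scenario_end_s",
            "event_file", "compression_file", "excluded", "exclusion_reason")
  if (!all(need %in% names(manifest)))
    stop_arg("manifest must have columns %s", paste(need, collapse = ", "))
  utils::write.csv(manifest[, need], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_arg("manifest does not exist: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$excluded <- as.logical(m$excluded)
  m
}

#' Read every team of a manifest into memory
#'
#' @param manifest_path path to a manifest written by [write_manifest()].
#' @return list with elements `manifest` (the table), `logs` (named list of
#'   `cpr_event_log`) and `series` (named list of `cpr_compression_series`;
#'   an unavailable series is represented with `available = FALSE`).
#' @export
read_cohort <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  logs <- list()
  series <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$team_id[i]
    logs[[id]] <- read_event_log(file.path(base, man$event_file[i]))
    series[[id]] <- if (is.na(man$compression_file[i]) ||
                        !nzchar(man$compression_file[i])) {
      compression_series(id, available = FALSE)
    } else {
      read_compression_series(file.path(base, man$compression_file[i]))
    }
  }
  list(manifest = man, logs = logs, series = series)
}
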