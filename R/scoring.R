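#' Names of the twelve scored performance variables, in rubric order
#' @export
PERFORMANCE_VARIABLES <- c(
  "no_flow_fraction", "avg_depth", "avg_rate",
  "t_first_rhythm", "t_first_shock",
  "n_compressor_changes", "dev_compressor_change",
  "n_adrenaline", "dev_adrenaline",
  "n_rhythm_checks", "dev_rhythm",
  "amiodarone_class")

#' Margin bands around a guideline threshold
#'
#' For "smaller is better" time variables the rubric awards 2 points at or
#' under the guideline threshold, 1 point within a margin above it, and 0
#' beyond: the score-1 band ends at `threshold * (1 + margin)` (e.g. a 120 s
#' threshold with a 15% margin gives bands at 120 s and 138 s).
#'
#' @param threshold guideline threshold (positive).
#' @param margin margin fraction (non-negative; 0 collapses the middle band).
#' @return named numeric `c(score2_upper, score1_upper)`.
#' @export
margin_bands <- function(threshold, margin) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop_arg("`threshold` must be positive")
  if (!is.numeric(margin) || margin < 0)
    stop_arg("`margin` must be non-negative")
  c(score2_upper = threshold, score1_upper = threshold * (1 + margin))
}

#' Margin bands for cycle-deviation variables
#'
#' Mean cycle deviations are scored on a band rescaled from the cycle target:
#' a deviation up to `margin * cycle_target` scores 2, up to twice that 1
#' (with the defaults, 18 s and 36 s).
#'
#' @param cycle_target cycle target in seconds (default 120).
#' @param margin margin fraction (default 0.15).
#' @return named numeric `c(score2_upper, score1_upper)`.
#' @export
deviation_bands <- function(cycle_target = 120, margin = 0.15) {
  if (cycle_target <= 0 || margin <= 0)
    stop_arg("cycle_target and margin must be positive")
  c(score2_upper = margin * cycle_target, score1_upper = 2 * margin * cycle_target)
}

#' Score an observed action count against the expected count
#'
#' Convention for the count variables (rhythm checks, compressor changes,
#' adrenaline doses): meeting or exceeding the expected number scores 2,
#' falling one action short scores 1, two or more short scores 0. The rule
#' is a configurable placeholder convention (see the rubric configuration).
#'
#' @param observed observed count.
#' @param expected expected count from [expected_count()].
#' @return 0, 1 or 2.
#' @export
score_expected_count <- function(observed, expected) {
  if (observed < 0 || expected < 0) stop_arg("counts must be non-negative")
  if (observed >= expected) 2L
  else if (observed == expected - 1) 1L
  else 0L
}

band_entry <- function(type, ...) c(list(type = type), list(...))

#' The default 0/1/2 scoring rubric
#'
#' One band definition per performance variable:
#' \itemize{
#'   \item no-flow fraction: 2 if <= 15%, 1 if <= 20%, else 0 (the 20% edge
#'     is a rubric constant, deliberately not derived from the margin rule);
#'   \item average depth: 2 inside 5--6 cm, else 0; missing data allowed;
#'   \item average rate: 2 inside 100--120 per minute, else 0; missing
#'     data allowed;
#'   \item times to first rhythm analysis / first shock: [margin_bands()] on
#'     the 120 s cycle target (120 s / 138 s); a team that never performed
#'     the action scores 0;
#'   \item cycle deviations (rhythm checks, compressor changes):
#'     [deviation_bands()] (18 s / 36 s);
#'   \item adrenaline deviation: 2 only for a mean deviation of exactly
#'     zero, else 0 (no middle band);
#'   \item action counts: [score_expected_count()] against the expected
#'     count for the scenario length;
#'   \item amiodarone: none 0, given at the wrong time 1, after the third
#'     shock 2.
#' }
#'
#' @param margin margin fraction (default 0.15).
#' @param targets an [algorithm_targets()] object.
#' @return a list of class `cpr_rubric`.
#' @export
default_rubric <- function(margin = 0.15, targets = algorithm_targets()) {
  mb <- margin_bands(targets$cycle_target, margin)
  db <- deviation_bands(targets$cycle_target, margin)
  structure(list(
    margin = margin,
    variables = list(
      no_flow_fraction = band_entry("upper_bands", score2_upper = 15,
                                    score1_upper = 20, absent = "error"),
      avg_depth = band_entry("target_range", low = 5, high = 6,
                             absent = "missing"),
      avg_rate = band_entry("target_range", low = 100, high = 120,
                            absent = "missing"),
      t_first_rhythm = band_entry("upper_bands",
                                  score2_upper = unname(mb[1]),
                                  score1_upper = unname(mb[2]), absent = "worst"),
      t_first_shock = band_entry("upper_bands",
                                 score2_upper = unname(mb[1]),
                                 score1_upper = unname(mb[2]), absent = "worst"),
      n_compressor_changes = band_entry("expected_count",
                                        kind = "compressor_change"),
      dev_compressor_change = band_entry("upper_bands",
                                         score2_upper = unname(db[1]),
                                         score1_upper = unname(db[2]),
                                         absent = "error"),
      n_adrenaline = band_entry("expected_count", kind = "adrenaline"),
      dev_adrenaline = band_entry("zero_only", tolerance = 1e-9,
                                  absent = "error"),
      n_rhythm_checks = band_entry("expected_count", kind = "rhythm_check"),
      dev_rhythm = band_entry("upper_bands",
                              score2_upper = unname(db[1]),
                              score1_upper = unname(db[2]), absent = "error"),
      amiodarone_class = band_entry("categorical",
                                    levels = list(NONE = 0L, GIVEN = 1L,
                                                  AFTER_THIRD_SHOCK = 2L))
    )), class = "cpr_rubric")
}

#' Score a single performance variable
#'
#' @param variable variable name (one of [PERFORMANCE_VARIABLES]).
#' @param value the measured value; `NA` for an absent measurement.
#' @param rubric a `cpr_rubric`.
#' @param expected expected count, required for the count variables.
#' @return integer 0, 1 or 2, or `NA` for a legitimately missing variable
#'   (compression depth/rate without simulator data).
#' @export
score_variable <- function(variable, value, rubric = default_rubric(),
                           expected = NULL) {
  spec <- rubric$variables[[variable]]
  if (is.null(spec)) stop_arg("rubric does not define variable '%s'", variable)
  if (spec$type != "expected_count" && (length(value) != 1))
    stop_arg("`value` must be a scalar")
  if (spec$type != "categorical" && is.na(value)) {
    return(switch(spec$absent %||% "error",
                  missing = NA_integer_,
                  worst = 0L,
                  stop_arg("variable '%s' must not be missing", variable)))
  }
  switch(spec$type,
    upper_bands = if (value <= spec$score2_upper) 2L
                  else if (value <= spec$score1_upper) 1L else 0L,
    target_range = if (value >= spec$low && value <= spec$high) 2L else 0L,
    zero_only = if (abs(value) <= (spec$tolerance %||% 0)) 2L else 0L,
    expected_count = {
      if (is.null(expected))
        stop_arg("variable '%s' needs an expected count", variable)
      score_expected_count(value, expected)
    },
    categorical = {
      s <- spec$levels[[as.character(value)]]
      if (is.null(s)) stop_arg("unknown level '%s' for variable '%s'",
                               value, variable)
      as.integer(s)
    },
    stop_arg("unknown rubric band type '%s'", spec$type))
}

#' Score one team's performance variables
#'
#' Applies the rubric to the twelve variables and averages the non-missing
#' scores into the CPR performance score. The only missingness handled is
#' the depth/rate pattern of failed simulator recordings (such teams are
#' scored on the remaining ten variables); more than two missing variables
#' is an error.
#'
#' @param vars a `cpr_performance` object from [compute_performance()].
#' @param rubric a `cpr_rubric`.
#' @param targets an [algorithm_targets()] object (for expected counts).
#' @return object of class `cpr_scorecard`: `team_id`, `group`, named
#'   integer vector `scores` (with `NA` for missing), `n_scored` and
#'   `cpr_score` (mean of the non-missing scores, in `[0, 2]`).
#' @export
score_team <- function(vars, rubric = default_rubric(),
                       targets = algorithm_targets()) {
  exp_counts <- list(
    n_compressor_changes = expected_count(vars$scenario_length,
                                          "compressor_change", targets),
    n_adrenaline = expected_count(vars$scenario_length, "adrenaline", targets),
    n_rhythm_checks = expected_count(vars$scenario_length, "rhythm_check",
                                     targets))
  scores <- vapply(PERFORMANCE_VARIABLES, function(v)
    score_variable(v, vars[[v]], rubric, expected = exp_counts[[v]]),
    integer(1))
  score_card(vars$team_id, scores, group = vars$group)
}

#' Assemble a scorecard from per-variable scores
#'
#' @param team_id team identifier.
#' @param scores named integer vector over [PERFORMANCE_VARIABLES]; `NA`
#'   marks a missing variable (at most two, the depth/rate pattern).
#' @param group study arm or `NA`.
#' @return a `cpr_scorecard`.
#' @export
score_card <- function(team_id, scores, group = NA_character_) {
  if (!all(PERFORMANCE_VARIABLES %in% names(scores)))
    stop_arg("scores must be named over the twelve performance variables")
  scores <- scores[PERFORMANCE_VARIABLES]
  if (sum(is.na(scores)) > 2)
    stop_arg("team '%s': more than two missing variables (only the depth/rate pattern is supported)",
             team_id)
  ok <- scores[!is.na(scores)]
  if (any(!ok %in% 0:2)) stop_arg("scores must be 0, 1 or 2")
  structure(list(team_id = as.character(team_id),
                 group = group,
                 scores = scores,
                 n_scored = length(ok),
                 cpr_score = mean(ok)),
            class = "cpr_scorecard")
}

#' @export
print.cpr_scorecard <- function(x, ...) {
  cat(sprintf("<cpr_scorecard> team %s: CPR performance score %.2f over %d variables\n",
              x$team_id, x$cpr_score, x$n_scored))
  invisible(x)
}

#' Scorecards of several teams as a data frame
#'
#' @param cards list of `cpr_scorecard` objects.
#' @return one row per team: `team_id`, `group`, one column per variable,
#'   `n_scored`, `cpr_score`.
#' @export
scorecard_table <- function(cards) {
  do.call(rbind, lapply(cards, function(c) {
    row <- data.frame(team_id = c$team_id, group = c$group,
                      stringsAsFactors = FALSE)
    for (v in PERFORMANCE_VARIABLES) row[[v]] <- c$scores[[v]]
    row$n_scored <- c$n_scored
    row$cpr_score <- c$cpr_score
    row
  }))
}

#' Per-group score distribution and raw-value summary
#'
#' For every group and variable: the share of teams at score 0, 1 and 2
#' (denominator: teams with the variable non-missing) and, for numeric
#' variables, the mean and SD of the raw value.
#'
#' @param cards list of `cpr_scorecard` objects.
#' @param perfs optional list of matching `cpr_performance` objects for the
#'   raw-value summaries.
#' @return data frame with columns `group`, `variable`, `n`, `p0`, `p1`,
#'   `p2` (shares in percent) and `mean`, `sd` of the raw variable (`NA`
#'   where not applicable).
#' @export
cohort_table <- function(cards, perfs = NULL) {
  if (!length(cards)) stop_arg("need at least one scorecard")
  sc <- scorecard_table(cards)
  pt <- if (!is.null(perfs)) performance_table(perfs) else NULL
  out <- list()
  for (g in unique(sc$group)) {
    sg <- sc[sc$group == g, , drop = FALSE]
    if (nrow(sg) == 0) stop_arg("empty group '%s'", g)
    for (v in PERFORMANCE_VARIABLES) {
      s <- sg[[v]]
      n <- sum(!is.na(s))
      p <- if (n > 0) 100 * tabulate(s[!is.na(s)] + 1L, 3L) / n else rep(NA_real_, 3)
      raw <- if (!is.null(pt) && is.numeric(pt[[v]]))
        pt[[v]][pt$group == g] else NULL
      out[[length(out) + 1]] <- data.frame(
        group = g, variable = v, n = n, p0 = p[1], p1 = p[2], p2 = p[3],
        mean = if (!is.null(raw)) mean(raw, na.rm = TRUE) else NA_real_,
        sd = if (!is.null(raw)) stats::sd(raw, na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Expected mean CPR performance score implied by score distributions
#'
#' Given per-variable score proportions for one group, the expected score of
#' each variable is \eqn{\sum_k k \, p(k)}. Teams with compression data are
#' scored on all twelve variables, teams without on the remaining ten
#' (depth/rate removed); the group expectation is the team-weighted average
#' of the two means. This is the consistency check connecting a score
#' distribution table to the group mean it implies.
#'
#' @param distributions data frame with columns `variable`, `p0`, `p1`,
#'   `p2` covering the twelve variables; proportions may be given as
#'   fractions or percentages and must sum to 1 (within 0.01) per variable.
#' @param n_total number of teams in the group.
#' @param n_missing_depth_rate number of teams without compression data.
#' @return the expected mean CPR performance score.
#' @export
expected_cohort_score <- function(distributions, n_total,
                                  n_missing_depth_rate) {
  need <- c("variable", "p0", "p1", "p2")
  if (!all(need %in% names(distributions)))
    stop_arg("distributions must have columns %s", paste(need, collapse = ", "))
  if (!all(PERFORMANCE_VARIABLES %in% distributions$variable))
    stop_arg("distributions must cover all twelve performance variables")
  if (n_missing_depth_rate > n_total)
    stop_arg("n_missing_depth_rate cannot exceed n_total")
  d <- distributions[match(PERFORMANCE_VARIABLES, distributions$variable), ]
  P <- as.matrix(d[, c("p0", "p1", "p2")])
  if (all(rowSums(P) > 50)) P <- P / 100  # percentages
  sums <- rowSums(P)
  if (any(abs(sums - 1) > 0.01))
    stop_arg("score proportions of '%s' sum to %.3f, not 1",
             d$variable[which.max(abs(sums - 1))], sums[which.max(abs(sums - 1))])
  P <- P / sums
  e <- P[, 2] + 2 * P[, 3]
  m12 <- mean(e)
  m10 <- mean(e[!PERFORMANCE_VARIABLES %in% c("avg_depth", "avg_rate")])
  ((n_total - n_missing_depth_rate) * m12 + n_missing_depth_rate * m10) / n_total
}

#' Write / read a rubric configuration
#'
#' The rubric is serialised as human-editable YAML (variable, band type,
#' edges) so corrected band definitions can be dropped in without code
#' changes.
#'
#' @param rubric a `cpr_rubric`.
#' @param path file path.
#' @return `write_rubric()` returns `path` invisibly; `read_rubric()` the
#'   rubric.
#' @export
write_rubric <- function(rubric, path) {
  yaml::write_yaml(unclass(rubric), path)
  invisible(path)
}

#' @rdname write_rubric
#' @export
read_rubric <- function(path) {
  r <- yaml::read_yaml(path)
  if (!all(PERFORMANCE_VARIABLES %in% names(r$variables)))
    stop_arg("rubric file must define all twelve performance variables")
  structure(r, class = "cpr_rubric")
}
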