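#' Pipeline run configuration
#'
#' Exactly one of `manifest` (a path to a cohort manifest on disk) or
#' `generator` (a list of [behavior_config()] objects, one per arm) must be
#' supplied.
#'
#' @param manifest path to a manifest written by [write_manifest()] /
#'   [simulate_cohort()].
#' @param generator list of `behavior_config` objects to simulate from.
#' @param rubric a `cpr_rubric` or a path to a rubric YAML.
#' @param targets an [algorithm_targets()] object.
#' @param out_dir directory for report tables (`NULL` for no files).
#' @param seed integer seed (used by the generator path).
#' @param verbose print progress messages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, generator = NULL,
                       rubric = default_rubric(),
                       targets = algorithm_targets(),
                       out_dir = NULL, seed = 1L, verbose = FALSE) {
  if (is.null(manifest) == is.null(generator))
    stop_arg("exactly one of `manifest` or `generator` must be given")
  if (is.character(rubric)) rubric <- read_rubric(rubric)
  structure(list(manifest = manifest, generator = generator, rubric = rubric,
                 targets = targets, out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the scoring pipeline over a cohort
#'
#' Orchestrates manifest (or generator) to metrics to scorecards to group
#' statistics: teams flagged `excluded` in the manifest are reported but not
#' scored; each remaining team's twelve performance variables are computed
#' and scored; the per-group score distribution table and the CPR
#' performance score comparison between arms are produced. With `out_dir`
#' set, writes `scorecards.csv`, `variable_summary.csv`, `comparison.csv`,
#' `exclusions.csv` and `run_log.txt` (software version and configuration
#' hash); reruns with the same configuration and seed reproduce the files
#' byte for byte.
#'
#' @param cfg a [run_config()].
#' @return object of class `cohort_result`: `scorecards` (list),
#'   `scorecard_table`, `performance`, `variable_summary`, `comparison`
#'   (a `cpr_comparison` for CPR score, CA_APP vs NO_APP, or `NULL` with a
#'   single group), `exclusions`, `n_by_group`.
#' @export
run_pipeline <- function(cfg) {
  say <- function(...) if (cfg$verbose) message(sprintf(...))

  if (!is.null(cfg$manifest)) {
    say("reading cohort from %s", cfg$manifest)
    cohort <- read_cohort(cfg$manifest)
  } else {
    say("simulating cohort (%d arm(s))", length(cfg$generator))
    parts <- lapply(cfg$generator, simulate_cohort)
    cohort <- list(
      manifest = do.call(rbind, lapply(parts, `[[`, "manifest")),
      logs = do.call(c, lapply(parts, `[[`, "logs")),
      series = do.call(c, lapply(parts, `[[`, "series")))
    rownames(cohort$manifest) <- NULL
  }
  man <- cohort$manifest

  excluded <- man[man$excluded, c("team_id", "group", "exclusion_reason"),
                  drop = FALSE]
  keep <- man$team_id[!man$excluded]
  if (!length(keep)) stop_arg("no teams left after exclusions")
  counts <- table(man$group[!man$excluded])
  if (any(counts == 0)) stop_arg("a group is empty after exclusions")
  say("scoring %d team(s); %d excluded", length(keep), nrow(excluded))

  perfs <- lapply(keep, function(id)
    compute_performance(cohort$logs[[id]], cohort$series[[id]], cfg$targets))
  names(perfs) <- keep
  cards <- lapply(perfs, score_team, rubric = cfg$rubric, targets = cfg$targets)
  sc_tab <- scorecard_table(cards)
  summary_tab <- cohort_table(cards, perfs)

  comparison <- NULL
  if (all(GROUPS %in% sc_tab$group)) {
    a <- sc_tab$cpr_score[sc_tab$group == "CA_APP"]
    b <- sc_tab$cpr_score[sc_tab$group == "NO_APP"]
    if (length(a) >= 2 && length(b) >= 2) comparison <- compare_groups(a, b)
  }

  res <- structure(list(
    scorecards = cards,
    scorecard_table = sc_tab,
    performance = performance_table(perfs),
    variable_summary = summary_tab,
    comparison = comparison,
    exclusions = excluded,
    n_by_group = counts), class = "cohort_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.csv(x, file.path(cfg$out_dir, f),
                                         row.names = FALSE, na = "NA")
    w(sc_tab, "scorecards.csv")
    w(summary_tab, "variable_summary.csv")
    w(excluded, "exclusions.csv")
    if (!is.null(comparison))
      w(data.frame(test = comparison$test, statistic = comparison$statistic,
                   p_value = comparison$p_value,
                   effect_name = names(comparison$effect),
                   effect = unname(comparison$effect),
                   mean_diff = comparison$mean_diff,
                   ci_low = comparison$ci[1], ci_high = comparison$ci[2]),
        "comparison.csv")
    writeLines(c(
      sprintf("cpraid version: %s",
              as.character(utils::packageVersion("cpraid"))),
      sprintf("seed: %d", cfg$seed),
      sprintf("config hash: %s",
              rlang::hash(cfg[c("manifest", "rubric", "targets", "seed")]))),
      file.path(cfg$out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s team(s)\n",
              paste(sprintf("%s: %d", names(x$n_by_group), x$n_by_group),
                    collapse = ", ")))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Inter-coder reliability of the event coding
#'
#' Reliability of the manual video coding is assessed on a subset of teams
#' coded independently by two raters over the six continuous reliability
#' variables (no-flow fraction, time to first rhythm check, time to first
#' shock, and the three cycle-deviation measures): the per-team, per-variable
#' values of the two coders enter an [icc_a1()] as paired ratings.
#'
#' @param coder1,coder2 data frames with a `team_id` column and the six
#'   reliability variables (`no_flow_fraction`, `t_first_rhythm`,
#'   `t_first_shock`, `dev_compressor_change`, `dev_adrenaline`,
#'   `dev_rhythm`), e.g. subsets of [performance_table()] output; both must
#'   cover the same teams.
#' @return an `icc_result`.
#' @export
reliability_check <- function(coder1, coder2) {
  vars <- c("no_flow_fraction", "t_first_rhythm", "t_first_shock",
            "dev_compressor_change", "dev_adrenaline", "dev_rhythm")
  for (d in list(coder1, coder2))
    if (!all(c("team_id", vars) %in% names(d)))
      stop_arg("coder tables need team_id and the six reliability variables")
  if (!setequal(coder1$team_id, coder2$team_id))
    stop_arg("the two coders must cover the same teams")
  coder2 <- coder2[match(coder1$team_id, coder2$team_id), , drop = FALSE]
  m <- cbind(as.vector(as.matrix(coder1[, vars])),
             as.vector(as.matrix(coder2[, vars])))
  icc_a1(m)
}
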