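# fixtures built in code, shared across test files

# a small fully guideline-conform log: compressions nearly continuous,
# checks/changes every 120 s, adrenaline every 240 s, amiodarone after shock 3
make_conform_log <- function(team_id = "FIX1", group = "CA_APP") {
  arrival <- 20
  checks <- arrival + seq(110, 710, by = 120)        # first well under 120 s
  pauses <- rep(8, length(checks))
  shocks <- checks + 6
  doses <- arrival + c(180, 420, 660)                # 240 s apart
  end <- 800 + arrival
  ev <- rbind(
    data.frame(kind = "COMPRESSIONS_START",
               timestamp = c(arrival + 5, checks + pauses)),
    data.frame(kind = "COMPRESSIONS_STOP", timestamp = c(checks, end)),
    data.frame(kind = "RHYTHM_CHECK_START", timestamp = checks),
    data.frame(kind = "RHYTHM_CHECK_END", timestamp = checks + 5),
    data.frame(kind = "DEFIBRILLATION", timestamp = shocks),
    data.frame(kind = "COMPRESSOR_CHANGE", timestamp = checks + 1),
    data.frame(kind = "ADRENALINE", timestamp = doses),
    data.frame(kind = "AMIODARONE", timestamp = shocks[3] + 20))
  event_log(team_id, group, arrival, end, ev)
}

# random but always-valid log for property tests (call inside with_seed)
random_valid_log <- function(team_id = "RND") {
  arrival <- runif(1, 0, 40)
  end <- arrival + runif(1, 200, 900)
  n_seg <- sample(1:6, 1)
  cuts <- sort(runif(2 * n_seg, arrival, end))
  starts <- cuts[seq(1, length(cuts), by = 2)]
  stops <- cuts[seq(2, length(cuts), by = 2)]
  ev <- rbind(
    data.frame(kind = "COMPRESSIONS_START", timestamp = starts),
    data.frame(kind = "COMPRESSIONS_STOP", timestamp = stops))
  n_chk <- sample(0:5, 1)
  if (n_chk > 0) {
    cs <- sort(runif(n_chk, arrival, end - 6))
    cs <- cs[c(TRUE, diff(cs) > 6)]  # keep checks apart so pairs do not nest
    ev <- rbind(ev,
      data.frame(kind = "RHYTHM_CHECK_START", timestamp = cs),
      data.frame(kind = "RHYTHM_CHECK_END", timestamp = cs + 3))
  }
  for (k in c("DEFIBRILLATION", "ADRENALINE", "COMPRESSOR_CHANGE")) {
    n <- sample(0:4, 1)
    if (n > 0)
      ev <- rbind(ev, data.frame(kind = k,
                                 timestamp = sort(runif(n, arrival, end))))
  }
  event_log(team_id, sample(GROUPS, 1), arrival, end, ev)
}

# independent oracle: no-flow fraction by a brute-force sweep over 1 s bins,
# accumulating the flow overlap bin by bin
no_flow_oracle <- function(log, bin = 1) {
  win <- cpraid:::arrest_window(log)
  ev <- log$events
  starts <- ev$timestamp[ev$kind == "COMPRESSIONS_START"]
  stops <- ev$timestamp[ev$kind == "COMPRESSIONS_STOP"]
  if (length(stops) < length(starts)) stops <- c(stops, win[2])
  edges <- seq(win[1], win[2], by = bin)
  if (edges[length(edges)] < win[2]) edges <- c(edges, win[2])
  flow <- 0
  for (j in seq_len(length(edges) - 1)) {
    if (length(starts))
      flow <- flow + sum(pmax(0, pmin(stops, edges[j + 1]) -
                                 pmax(starts, edges[j])))
  }
  100 * (1 - flow / (win[2] - win[1]))
}

# independent oracle: mean cycle delay by explicit loop
interval_deviation_oracle <- function(timestamps, target, origin = 0) {
  if (!length(timestamps)) return(NA_real_)
  prev <- origin
  devs <- numeric(0)
  for (t in timestamps) {
    gap <- t - prev
    devs <- c(devs, if (gap > target) gap - target else 0)
    prev <- t
  }
  mean(devs)
}

# mean of a normal truncated below at zero (closed form)
truncnorm_mean_oracle <- function(mu, sd) {
  if (sd <= 0) return(max(mu, 0))
  a <- mu / sd
  mu + sd * dnorm(a) / pnorm(a)
}

# a full set of guideline-perfect scores
perfect_scores <- function() {
  s <- rep(2L, length(PERFORMANCE_VARIABLES))
  names(s) <- PERFORMANCE_VARIABLES
  s
}
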