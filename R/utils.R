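# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# serialise doubles with enough digits to round-trip exactly; a shorter
# representation can re-order values that sit on a shared boundary (e.g. the
# last event vs scenario_end)
fmt17 <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

# one draw set from a normal truncated below at `lower` (inverse-CDF method;
# deviations in this domain are one-sided, hence the truncation)
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  # guard u == 1 from floating point
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

# mean of a normal(mean, sd) truncated below at 0
truncnorm_mean <- function(mean, sd) {
  if (sd <= 0) return(max(mean, 0))
  a <- mean / sd
  mean + sd * stats::dnorm(a) / stats::pnorm(a)
}

# run `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a reproducible child seed (kept within 32-bit integer range)
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 7919) %% 2147483647)
}
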