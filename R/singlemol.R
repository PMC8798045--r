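#' Single-molecule dwell times within an observation interval
#'
#' Selects binding events whose start time `t_on` falls in `[t0, t1)`,
#' computes residence durations `t_off - t_on`, and reports the arithmetic
#' mean with its sample standard error. Events truncated by the observation
#' boundary are excluded by default (`censor = "exclude"`); with
#' `censor = "include"` their visible duration enters as a lower bound.
#' Events straddling the interval boundary are assigned by `t_on` and not
#' split.
#'
#' @param events data.frame with columns `t_on`, `t_off` and optionally
#'   `censored` (assumed `FALSE` when absent).
#' @param interval numeric `c(t0, t1)` in s; `NULL` selects all events.
#' @param censor `"exclude"` or `"include"`.
#' @return List with `durations`, `mean`, `se`, `n`; an empty selection
#'   yields `n = 0` and `NA` statistics.
#' @export
dwell_times <- function(events, interval = NULL,
                        censor = c("exclude", "include")) {
  censor <- match.arg(censor)
  stopifnot(is.data.frame(events), all(c("t_on", "t_off") %in% names(events)))
  if (any(events$t_off <= events$t_on))
    stop("dwell_times: every event needs t_off > t_on")
  cens <- if ("censored" %in% names(events)) events$censored else
    rep(FALSE, nrow(events))
  keep <- if (censor == "exclude") !cens else rep(TRUE, nrow(events))
  if (!is.null(interval))
    keep <- keep & events$t_on >= interval[1L] & events$t_on < interval[2L]
  d <- events$t_off[keep] - events$t_on[keep]
  n <- length(d)
  list(durations = d,
       mean = if (n > 0L) mean(d) else NA_real_,
       se = if (n > 1L) stats::sd(d) / sqrt(n) else NA_real_,
       n = n)
}

#' Empirical cumulative distribution of dwell times
#'
#' Right-continuous step ECDF rising from 0 to 1, returned both as a
#' function and as a step table for plotting/export.
#'
#' @param durations positive dwell times (s), at least one.
#' @return List with `fun` (a [stats::ecdf()] function) and `table`
#'   (data.frame `t`, `F`).
#' @export
dwell_ecdf <- function(durations) {
  if (length(durations) < 1L) stop("dwell_ecdf: need >= 1 duration")
  f <- stats::ecdf(durations)
  t_sorted <- sort(unique(durations))
  list(fun = f, table = data.frame(t = t_sorted, F = f(t_sorted)))
}

#' Association rate per microtubule length and concentration
#'
#' `rate = n_events / (duration * total_mt_length * conc)`, in events
#' um^-1 nM^-1 s^-1, with Poisson counting error
#' `sqrt(n_events)` over the same denominator.
#'
#' @param n_events number of binding events observed.
#' @param duration observation time (s), > 0.
#' @param total_mt_length summed microtubule length (um), > 0.
#' @param conc probe concentration (nM), > 0.
#' @return Named numeric `c(rate, se)`.
#' @export
association_rate <- function(n_events, duration, total_mt_length, conc) {
  if (duration <= 0 || total_mt_length <= 0 || conc <= 0)
    stop("association_rate: duration, length and concentration must be > 0")
  if (n_events < 0) stop("association_rate: n_events must be >= 0")
  denom <- duration * total_mt_length * conc
  c(rate = n_events / denom, se = sqrt(n_events) / denom)
}

#' Compare dwell-time distributions between conditions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between two dwell-time
#' samples, e.g. single-molecule control versus spiking.
#'
#' @param durations_a,durations_b non-empty numeric vectors (s).
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_conditions <- function(durations_a, durations_b) {
  if (length(durations_a) < 1L || length(durations_b) < 1L)
    stop("compare_conditions: both samples must be non-empty")
  stats::wilcox.test(durations_a, durations_b, alternative = "two.sided",
                     exact = length(durations_a) < 50 &&
                       length(durations_b) < 50)
}
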