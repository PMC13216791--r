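#' @title Diagnostic-accuracy evaluation
#' @description Scores system entry events against a gold-standard
#'   observer log at the observation level and computes sensitivity and
#'   specificity with 95% confidence intervals, plus the sample-size /
#'   interval-half-width planner used to size a validation study.
#' @name diagnostics
NULL

#' Build or read an observation log
#'
#' One row per monitored observation window (e.g. one room entry by
#' healthcare personnel), with the observer's verdict on whether the zone
#' was entered. Windows are closed `[start_s, end_s]` and need not be
#' disjoint.
#'
#' @param observation_id character ids.
#' @param start_s,end_s window bounds in seconds, `start_s < end_s`.
#' @param gold_entered logical observer verdict.
#' @return data frame of class `observation_log` with columns
#'   `observation_id`, `start_s`, `end_s`, `gold_entered` and an unset
#'   `system_entered` column.
#' @export
observation_log <- function(observation_id, start_s, end_s, gold_entered) {
  df <- data.frame(observation_id = as.character(observation_id),
                   start_s = as.double(start_s), end_s = as.double(end_s),
                   gold_entered = as.logical(gold_entered),
                   system_entered = NA)
  if (any(df$start_s >= df$end_s)) stop("observation windows need start_s < end_s")
  class(df) <- c("observation_log", "data.frame")
  df
}

#' @rdname observation_log
#' @param path CSV with columns `observation_id`, `start_s`, `end_s`,
#'   `gold_entered` (0/1 or logical).
#' @export
read_gold_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observation_log(df$observation_id, df$start_s, df$end_s,
                  as.logical(df$gold_entered))
}

#' Fill system verdicts from entry events
#'
#' An observation is system-positive iff at least one entry event
#' timestamp falls inside its closed window; multiple events in one window
#' count once (the verdict is binary per observation, so duplicate counts
#' cannot alter sensitivity or specificity). Events matching no window are
#' not dropped silently: they are returned in a `spillover` attribute for
#' audit.
#'
#' @param events entry-event data frame from [count_entries()] (needs a
#'   `timestamp_s` column).
#' @param observations an [observation_log()].
#' @return the observation log with `system_entered` filled; attribute
#'   `spillover` holds events outside every window.
#' @export
classify_observations <- function(events, observations) {
  stopifnot(inherits(observations, "observation_log"))
  ts <- events$timestamp_s
  obs <- observations
  obs$system_entered <- vapply(seq_len(nrow(obs)), function(i) {
    any(ts >= obs$start_s[i] & ts <= obs$end_s[i])
  }, logical(1))
  in_any <- vapply(ts, function(t) {
    any(t >= obs$start_s & t <= obs$end_s)
  }, logical(1))
  attr(obs, "spillover") <- events[!in_any, , drop = FALSE]
  obs
}

#' Paired confusion counts
#'
#' @param observations a classified [observation_log()] (all
#'   `system_entered` verdicts filled).
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(observations) {
  stopifnot(inherits(observations, "observation_log"),
            !anyNA(observations$system_entered))
  g <- observations$gold_entered
  s <- observations$system_entered
  structure(list(tp = sum(g & s), fn = sum(g & !s),
                 fp = sum(!g & s), tn = sum(!g & !s)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' `[0, 1]`. Wilson and Clopper-Pearson alternatives (statistically
#' preferable near the boundary) are available through
#' [diagnostic_stats()].
#'
#' @param p_hat estimated proportion in `[0, 1]`.
#' @param n denominator, >= 1.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`, unrounded.
#' @export
wald_ci <- function(p_hat, n, level = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1, level > 0, level < 1)
  if (n < 1) stop("wald_ci needs n >= 1")
  z <- stats::qnorm((1 + level) / 2)
  hw <- z * sqrt(p_hat * (1 - p_hat) / n)
  c(low = max(0, p_hat - hw), high = min(1, p_hat + hw))
}

.prop_ci <- function(x, n, level, method) {
  switch(method,
         wald = wald_ci(x / n, n, level),
         wilson = {
           ci <- stats::prop.test(x, n, conf.level = level,
                                  correct = FALSE)$conf.int
           c(low = ci[1], high = ci[2])
         },
         `clopper-pearson` = {
           ci <- stats::binom.test(x, n, conf.level = level)$conf.int
           c(low = ci[1], high = ci[2])
         },
         stop("unknown ci_method: ", method))
}

#' Confidence-interval half-width, in percentage points
#'
#' `z * sqrt(p(1-p)/n)`, on the percent scale: the planning quantity for
#' "a 95% interval of +/- H% at n observations".
#'
#' @inheritParams wald_ci
#' @param p assumed proportion.
#' @return half-width in percentage points.
#' @export
ci_half_width <- function(p, n, level = 0.95) {
  stopifnot(p >= 0, p <= 1)
  if (n < 1) stop("ci_half_width needs n >= 1")
  z <- stats::qnorm((1 + level) / 2)
  100 * z * sqrt(p * (1 - p) / n)
}

#' Smallest sample size achieving a target interval half-width
#'
#' Smallest integer `n` with `ci_half_width(p, n, level) <= half_width`
#' (ceiling of the closed form `z^2 p(1-p) / w^2`).
#'
#' @param p assumed proportion.
#' @param half_width target half-width in percentage points (> 0).
#' @param level confidence level.
#' @return integer sample size (1 when `half_width >= 100`).
#' @export
sample_size_for_half_width <- function(p, half_width, level = 0.95) {
  stopifnot(half_width > 0, p >= 0, p <= 1)
  if (half_width >= 100) return(1L)
  z <- stats::qnorm((1 + level) / 2)
  n <- ceiling(z^2 * p * (1 - p) / (half_width / 100)^2)
  n <- max(1L, as.integer(n))
  # guard against floating-point edge of the ceiling
  while (ci_half_width(p, n, level) > half_width) n <- n + 1L
  while (n > 1L && ci_half_width(p, n - 1L, level) <= half_width) n <- n - 1L
  n
}

#' Sensitivity and specificity with confidence intervals
#'
#' Sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)`, each with a
#' confidence interval computed on its own denominator (gold-positive
#' count for sensitivity, gold-negative for specificity). A statistic with
#' a zero denominator raises an error of class `zonewatch_no_denominator`
#' rather than silently returning 0.
#'
#' @param counts a [confusion()] result.
#' @param level confidence level.
#' @param ci_method `"wald"` (default), `"wilson"` or
#'   `"clopper-pearson"`.
#' @return list of class `diagnostic_stats` with `sensitivity`,
#'   `specificity`, `sens_ci`, `spec_ci`, `n_pos`, `n_neg`, `ci_method`,
#'   `level`. Values are unrounded; the print method displays the
#'   conventional 2-decimal presentation.
#' @export
diagnostic_stats <- function(counts, level = 0.95,
                             ci_method = c("wald", "wilson",
                                           "clopper-pearson")) {
  stopifnot(inherits(counts, "confusion_counts"))
  ci_method <- match.arg(ci_method)
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  if (n_pos == 0L) {
    stop(errorCondition("no gold-positive observations: sensitivity undefined",
                        class = c("zonewatch_no_denominator", "error",
                                  "condition")))
  }
  if (n_neg == 0L) {
    stop(errorCondition("no gold-negative observations: specificity undefined",
                        class = c("zonewatch_no_denominator", "error",
                                  "condition")))
  }
  sens <- counts$tp / n_pos
  spec <- counts$tn / n_neg
  structure(list(sensitivity = sens, specificity = spec,
                 sens_ci = .prop_ci(counts$tp, n_pos, level, ci_method),
                 spec_ci = .prop_ci(counts$tn, n_neg, level, ci_method),
                 n_pos = n_pos, n_neg = n_neg,
                 ci_method = ci_method, level = level),
            class = "diagnostic_stats")
}

#' @export
print.diagnostic_stats <- function(x, ...) {
  cat(sprintf("sensitivity %.2f (%d%% CI, %.2f-%.2f; n=%d)\n",
              x$sensitivity, round(100 * x$level), x$sens_ci[1],
              x$sens_ci[2], x$n_pos))
  cat(sprintf("specificity %.2f (%d%% CI, %.2f-%.2f; n=%d)\n",
              x$specificity, round(100 * x$level), x$spec_ci[1],
              x$spec_ci[2], x$n_neg))
  cat(sprintf("CI method: %s\n", x$ci_method))
  invisible(x)
}

#' Format accuracy results as a phase table
#'
#' @param stats_list named list of `diagnostic_stats` (names are row
#'   labels, e.g. study phases).
#' @return data frame with columns `phase`, `sensitivity`, `sens_ci`,
#'   `specificity`, `spec_ci`, bounds rendered at 2 decimals.
#' @export
stats_table <- function(stats_list) {
  fmt <- function(ci) sprintf("%.2f-%.2f", ci[1], ci[2])
  do.call(rbind, lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    data.frame(phase = nm,
               sensitivity = round(s$sensitivity, 2),
               sens_ci = fmt(s$sens_ci),
               specificity = round(s$specificity, 2),
               spec_ci = fmt(s$spec_ci))
  }))
}

#' Simulate an observation-level validation study
#'
#' Generates `n` observation windows with a gold verdict drawn at
#' `prevalence`, then injects per-observation misclassification: a
#' gold-positive window receives a system entry event with probability
#' `sensitivity`, a gold-negative one with probability `1 - specificity`.
#' The output flows through [classify_observations()], [confusion()] and
#' [diagnostic_stats()] exactly like real pipeline output, so estimator
#' recovery can be checked end to end.
#'
#' @param n number of observations.
#' @param sensitivity,specificity true operating characteristics to
#'   inject.
#' @param prevalence probability an observation is gold-positive.
#' @param seed RNG seed.
#' @param window_s observation window length, seconds.
#' @return list with `observations` (an [observation_log()]) and `events`
#'   (entry-event data frame).
#' @export
simulate_observation_study <- function(n, sensitivity, specificity,
                                       prevalence = 0.5, seed = 1,
                                       window_s = 8) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    start <- (seq_len(n) - 1) * (window_s + 2)
    gold <- stats::runif(n) < prevalence
    fire <- ifelse(gold, stats::runif(n) < sensitivity,
                   stats::runif(n) < (1 - specificity))
    obs <- observation_log(sprintf("obs%04d", seq_len(n)), start,
                           start + window_s, gold)
    ev_t <- start[fire] + window_s / 2
    events <- data.frame(zone_label = "red zone",
                         track_id = seq_along(ev_t),
                         frame_index = as.integer(round(ev_t * 30)),
                         timestamp_s = ev_t)
    list(observations = obs, events = events)
  })
}
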