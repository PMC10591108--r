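# Kaplan-Meier estimation, Greenwood variance, fixed-horizon survival
# extraction, median-expression grouping and the two-group log-rank test.
# Product-limit and log-rank computations are delegated to the survival
# package; this module fixes the conventions (CI scale, step evaluation,
# tie rules) and the tabular interfaces the pipeline uses.

#' Kaplan-Meier curve with Greenwood variance
#'
#' Product-limit estimate with Greenwood variance and 95% confidence
#' intervals, by default on the complementary log-log scale (clipped to
#' `[0, 1]`). Censoring at an event time is processed after the deaths at
#' that time (standard risk-set rule).
#'
#' @param table data frame with `time` (>= 0) and `event` (1 = death,
#'   0 = censored) columns.
#' @param conf_type CI scale: `"cloglog"` (default), `"plain"` or `"log"`.
#' @param conf_level confidence level (default 0.95).
#' @return a `km_curve` data frame: time, n_risk, n_event, n_censor, surv,
#'   greenwood_var, lower, upper; one row per distinct observed time.
#' @export
km_estimate <- function(table, conf_type = c("cloglog", "plain", "log"),
                        conf_level = 0.95) {
  conf_type <- match.arg(conf_type)
  assert_that(nrow(table) >= 1, "need at least one subject")
  assert_that(all(table$time >= 0), "validation error: negative time")
  assert_that(all(table$event %in% c(0, 1)),
              "validation error: event must be 0/1")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = table,
    conf.type = switch(conf_type, cloglog = "log-log", plain = "plain",
                       log = "log"),
    conf.int = conf_level)
  curve <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    # survfit std.err is the SE of the cumulative hazard; Greenwood variance
    # of S(t) is S(t)^2 times its square
    greenwood_var = (fit$surv * fit$std.err)^2,
    lower = pmax(0, ifelse(is.na(fit$lower) & fit$surv %in% c(0, 1),
                           fit$surv, fit$lower)),
    upper = pmin(1, ifelse(is.na(fit$upper) & fit$surv %in% c(0, 1),
                           fit$surv, fit$upper)))
  curve$greenwood_var[curve$surv == 0] <- 0
  class(curve) <- c("km_curve", "data.frame")
  curve
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function lookup: the estimate at `t` is the value
#' at the last observed time `<= t` (1 before the first). Evaluation beyond
#' the last observed time returns the last value with `extrapolated = TRUE`.
#'
#' @param curve a [km_estimate()] result.
#' @param t non-negative time (e.g. 60 months for 5-year survival).
#' @return list: estimate, lower, upper, extrapolated.
#' @export
survival_at <- function(curve, t) {
  assert_that(t >= 0, "t must be >= 0")
  idx <- which(curve$time <= t)
  if (!length(idx)) {
    return(list(estimate = 1, lower = 1, upper = 1, extrapolated = FALSE))
  }
  i <- max(idx)
  list(estimate = curve$surv[i], lower = curve$lower[i],
       upper = curve$upper[i], extrapolated = t > max(curve$time))
}

#' Two-group log-rank test
#'
#' (O - E)^2 form with hypergeometric variance summed over event times;
#' p from a chi-squared with 1 df.
#'
#' @param table survival data frame with `time` and `event` columns.
#' @param group vector (length nrow(table)) with exactly two non-empty
#'   levels, or the name of a column of `table`.
#' @return list: chi2, p, n per group.
#' @export
logrank <- function(table, group) {
  if (length(group) == 1 && is.character(group) && group %in% names(table)) {
    group <- table[[group]]
  }
  assert_that(length(group) == nrow(table),
              "group must match the table rows")
  g <- factor(group)
  assert_that(nlevels(g) == 2 && all(table(g) > 0),
              "log-rank requires exactly 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(table, g = g))
  list(chi2 = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n))
}

#' Median split of a per-patient score
#'
#' `low` = score <= median, `high` = score > median: ties at the median go
#' to the low group.
#'
#' @param expr numeric vector (e.g. mean target-gene expression), length
#'   >= 2.
#' @return factor of `"low"` / `"high"`, same order as `expr`.
#' @export
median_split <- function(expr) {
  assert_that(length(expr) >= 2, "need >= 2 patients")
  m <- stats::median(expr)
  labels <- ifelse(expr <= m, "low", "high")
  assert_that(length(unique(labels)) == 2,
              "all scores equal: median split yields a single group")
  factor(labels, levels = c("low", "high"))
}
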