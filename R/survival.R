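## Product-limit (Kaplan-Meier) survivorship with right-censoring.
## The estimator itself is delegated to survival::survfit; this module
## fixes the package-wide conventions (quantile definition, tie handling)
## and the curve container used by the cohort parameter extraction.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' distinct event times; censored durations leave the risk set after their
#' time (events precede censorings at tied times, the standard
#' convention).
#'
#' @param durations observation times in years (>= 0).
#' @param events logical; `TRUE` = death observed, `FALSE` = right-censored.
#' @return a `kelp_km` object: data frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, plus `n` and the underlying `survfit` fit.
#' @export
km_fit <- function(durations, events) {
  if (length(durations) == 0) stopf("no observations for survival fit")
  if (length(durations) != length(events))
    stopf("durations and events differ in length")
  if (any(durations < 0)) stopf("negative durations")
  fit <- survival::survfit(survival::Surv(durations, as.integer(events)) ~ 1,
                           conf.type = "none")
  structure(list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event,
                                    n_censor = fit$n.censor, surv = fit$surv),
                 n = length(durations), n_events = sum(events),
                 fit = fit),
            class = "kelp_km")
}

#' Survival quantile
#'
#' The p-th survival quantile is the smallest event time `t` with
#' `S(t) <= 1 - p`. When the curve never drops that low (heavy censoring),
#' the quantile is undefined and `NA` is returned.
#'
#' @param km a `kelp_km` object.
#' @param p probabilities in (0, 1).
#' @return numeric vector of times (years), `NA` where undefined.
#' @export
km_quantile <- function(km, p) {
  curve <- km$curve[km$curve$n_event > 0, ]
  vapply(p, function(pp) {
    hit <- which(curve$surv <= 1 - pp + 1e-12)
    if (length(hit)) curve$time[hit[1]] else NA_real_
  }, 0)
}

#' Pooled survival curves by group
#'
#' One Kaplan-Meier curve per group of plants (all cohorts pooled within a
#' site, or per cohort). Groups with no plants are omitted.
#'
#' @param plants a `kelp_plants` table, with `cohort_id` assigned if
#'   grouping by cohort.
#' @param group `"site"` or `"cohort"`.
#' @param convention death-time convention passed to [lifespan()].
#' @return named list of `kelp_km` objects.
#' @export
pooled_site_curves <- function(plants, group = c("site", "cohort"),
                               convention = "midpoint") {
  group <- match.arg(group)
  key <- if (group == "site") plants$site_id else plants$cohort_id
  keep <- !is.na(key)
  ls <- lifespan(plants[keep, , drop = FALSE], convention)
  out <- lapply(split(ls, key[keep]), function(g) km_fit(g$duration, g$event))
  out[order(names(out))]
}

#' @export
print.kelp_km <- function(x, ...) {
  med <- km_quantile(x, 0.5)
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median survival = %s yr\n",
              x$n, x$n_events,
              if (is.na(med)) "not reached" else format(med, digits = 3)))
  invisible(x)
}

#' @export
plot.kelp_km <- function(x, xlab = "Years since adult recruitment",
                         ylab = "Survival", ...) {
  graphics::plot(c(0, x$curve$time), c(1, x$curve$surv), type = "s",
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
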