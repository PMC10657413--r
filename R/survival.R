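#' Surrogate-mortality event times from tumor-volume series
#'
#' Converts each animal's volume series into a surrogate survival record at
#' a tumor-volume endpoint (default 1200 mm^3, the conventional surrogate
#' for mortality in preclinical efficacy studies). The event time is the
#' first measurement day with volume at or above the threshold — no
#' interpolation between scheduled measurement days, and a tumor that
#' crosses then regresses still has its event at the first crossing.
#' Animals that never reach the threshold are censored at their last
#' measured day.
#'
#' @param data A measurement table.
#' @param threshold Endpoint tumor volume in mm^3, default 1200.
#' @return A tibble of survival records: `animal_id`, `group`, `time`
#'   (study day), `event` (1 = endpoint reached, 0 = censored).
#' @export
surrogate_events <- function(data, threshold = 1200) {
  tbl <- as_tibble(data) %>%
    dplyr::filter(!is.na(.data$volume)) %>%
    dplyr::arrange(.data$animal_id, .data$day)
  if (nrow(tbl) == 0) {
    abort("surrogate_events(): no volume measurements in the table.",
          class = "tumorgri_validation_error")
  }
  tbl %>%
    dplyr::group_by(.data$animal_id, .data$group) %>%
    dplyr::summarise(
      time = if (any(.data$volume >= threshold)) {
        .data$day[which(.data$volume >= threshold)[1]]
      } else {
        max(.data$day)
      },
      event = as.integer(any(.data$volume >= threshold)),
      .groups = "drop"
    )
}

#' Kaplan-Meier product-limit curves for surrogate survival records
#'
#' Standard product-limit estimate with right censoring (ties between
#' events and censorings at the same time are handled events-first, the
#' product-limit convention). One curve per arm when a `group` column is
#' present.
#'
#' @param records Survival records from [surrogate_events()] (columns
#'   `time`, `event`, optionally `group`).
#' @return A tibble of class `km_curve`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, one row per distinct observed time
#'   within each arm. Plot with [autoplot()].
#' @export
km_estimate <- function(records) {
  tbl <- as_tibble(records)
  if (nrow(tbl) == 0) {
    abort("km_estimate(): no survival records supplied.",
          class = "tumorgri_validation_error")
  }
  if (!("group" %in% names(tbl))) tbl$group <- "all"
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = tbl, conf.type = "none"
  )
  strata <- if (is.null(fit$strata)) {
    rep(unique(tbl$group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(
    group = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-sided log-rank test between arms
#'
#' Standard (unweighted) log-rank test comparing surrogate survival between
#' arms: at each distinct event time the observed events per arm are
#' compared with their hypergeometric expectation given the risk sets, with
#' the tie-corrected hypergeometric variance; the accumulated statistic is
#' referred to a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param records Survival records with a `group` column holding two or
#'   more arms.
#' @return An object of class `logrank_result` with fields `chi_square`,
#'   `df`, `p_value`, `n` (per-arm sizes), `observed`, `expected`. Use
#'   [tidy()] for a one-row tibble.
#' @export
logrank_test <- function(records) {
  tbl <- as_tibble(records)
  if (!("group" %in% names(tbl))) {
    abort("logrank_test(): records need a group column.",
          class = "tumorgri_validation_error")
  }
  groups <- unique(tbl$group)
  if (length(groups) < 2 || any(table(tbl$group) < 1)) {
    abort("logrank_test(): need at least two arms with >= 1 record each.",
          class = "tumorgri_validation_error")
  }
  if (sum(tbl$event) == 0) {
    abort("logrank_test(): no events in any arm; the test is degenerate.",
          class = "tumorgri_degenerate_error")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tbl)
  df <- length(sd$n) - 1
  chi <- unname(sd$chisq)
  structure(
    list(
      chi_square = chi, df = df,
      p_value = pchisq(chi, df = df, lower.tail = FALSE),
      n = setNames(as.integer(sd$n), sub("^group=", "", names(sd$n))),
      observed = sd$obs, expected = sd$exp
    ),
    class = "logrank_result"
  )
}

# per-arm median surrogate survival (smallest time with S(t) <= 0.5; NA if
# the curve never falls to 0.5)
median_survival <- function(records) {
  km_estimate(records) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      median_survival = if (any(.data$survival <= 0.5)) {
        min(.data$time[.data$survival <= 0.5])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}
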