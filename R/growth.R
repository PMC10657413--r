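#' Fit per-animal exponential tumor-growth rates
#'
#' Fits each animal's tumor-volume series to a simple exponential growth
#' model `V(t) = V0 * exp(r * t)` by ordinary least squares of
#' `log(max(volume, floor))` against study day. The slope `r` is the
#' per-day exponential growth rate; a complete-response series (volumes
#' recorded as 0) contributes a strongly negative, finite rate through the
#' floor.
#'
#' The floor exists because the log transform is undefined at 0; the
#' `floored` flag marks animals whose series touched it, so a sensitivity
#' analysis on the floor is always possible. Animals with fewer than 2
#' usable points inside the window are excluded with a warning and do not
#' appear in the result.
#'
#' @param data A measurement table (see [as_measurement_table()]).
#' @param window Optional `c(day_lo, day_hi)`; only measurements with
#'   `day_lo <= day <= day_hi` enter the fit. `NULL` uses all days. A
#'   "rate on Day d" in the field's usage corresponds to `window = c(0, d)`.
#' @param floor Volume floor in mm^3 applied before the log transform;
#'   must be > 0. Default 1.
#'
#' @return A tibble with one row per fitted animal: `animal_id`, `group`,
#'   `rate` (per day), `log_intercept` (log mm^3 at day 0), `rate_se`
#'   (standard OLS slope SE; 0 when residuals vanish), `n_points`,
#'   `floored`, `day_lo`, `day_hi`.
#' @examples
#' tbl <- tibble::tibble(
#'   animal_id = rep("m1", 4), group = "vehicle", day = c(0, 3, 7, 10),
#'   volume = 100 * exp(0.2 * c(0, 3, 7, 10))
#' )
#' fit_growth(tbl)
#' @export
fit_growth <- function(data, window = NULL, floor = 1) {
  if (!is.numeric(floor) || length(floor) != 1 || is.na(floor) || floor <= 0) {
    abort("fit_growth(): floor must be a single positive number (mm^3).",
          class = "tumorgri_validation_error")
  }
  tbl <- as_tibble(data)
  if (!all(c("animal_id", "group", "day", "volume") %in% names(tbl))) {
    abort("fit_growth(): data needs animal_id, group, day, volume columns.",
          class = "tumorgri_validation_error")
  }
  day_lo <- if (is.null(window)) -Inf else window[1]
  day_hi <- if (is.null(window)) Inf else window[2]
  use <- tbl %>%
    dplyr::filter(!is.na(.data$volume), !is.na(.data$day),
                  .data$day >= day_lo, .data$day <= day_hi)

  counts <- dplyr::count(use, .data$animal_id)
  all_animals <- unique(tbl$animal_id)
  short <- union(setdiff(all_animals, counts$animal_id),
                 counts$animal_id[counts$n < 2])
  if (length(short) > 0) {
    warn(paste0(
      "fit_growth(): excluding ", length(short),
      " animal(s) with < 2 usable points in the fitting window: ",
      paste(sort(short), collapse = ", ")
    ))
  }
  use <- dplyr::filter(use, !(.data$animal_id %in% short))
  if (nrow(use) == 0) {
    abort("fit_growth(): no animal has >= 2 usable points in the window.",
          class = "tumorgri_insufficient_data_error")
  }

  # closed-form OLS of log(floored volume) on day, per animal
  use %>%
    dplyr::mutate(lv = log(pmax(.data$volume, floor)),
                  flo = .data$volume < floor) %>%
    dplyr::group_by(.data$animal_id, .data$group) %>%
    dplyr::summarise(
      n_points = dplyr::n(),
      xbar = mean(.data$day),
      ybar = mean(.data$lv),
      sxx = sum((.data$day - .data$xbar)^2),
      sxy = sum((.data$day - .data$xbar) * (.data$lv - .data$ybar)),
      syy = sum((.data$lv - .data$ybar)^2),
      floored = any(.data$flo),
      day_lo = min(.data$day),
      day_hi = max(.data$day),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      rate = .data$sxy / .data$sxx,
      log_intercept = .data$ybar - .data$rate * .data$xbar,
      rss = pmax(.data$syy - .data$rate * .data$sxy, 0),
      rate_se = dplyr::if_else(
        .data$n_points > 2,
        sqrt(.data$rss / (.data$n_points - 2) / .data$sxx),
        0
      )
    ) %>%
    dplyr::select("animal_id", "group", "rate", "log_intercept", "rate_se",
                  "n_points", "floored", "day_lo", "day_hi")
}

#' Summarize per-arm mean growth rates
#'
#' Aggregates per-animal exponential growth rates into per-arm summaries:
#' the arithmetic mean rate, its standard error from the between-animal
#' spread (`sd(rates)/sqrt(n)`), and `df = n - 1`. Per-animal fit
#' uncertainty (`rate_se`) is deliberately not propagated: the downstream
#' tests compare arms through between-animal variability, which already
#' contains the within-animal fitting noise.
#'
#' @param fits A per-animal fits tibble from [fit_growth()] (needs
#'   `animal_id`, `group`, `rate`).
#' @return A tibble with one row per arm: `group`, `n`, `mean_rate`, `se`,
#'   `df`, and `rates` (list column of the per-animal rates).
#' @export
summarize_groups <- function(fits) {
  tbl <- as_tibble(fits)
  if (!all(c("group", "rate") %in% names(tbl))) {
    abort("summarize_groups(): fits needs group and rate columns.",
          class = "tumorgri_validation_error")
  }
  out <- tbl %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_rate = mean(.data$rate),
      se = stats::sd(.data$rate) / sqrt(dplyr::n()),
      df = dplyr::n() - 1,
      rates = list(.data$rate),
      .groups = "drop"
    )
  small <- out$group[out$n < 2]
  if (length(small) > 0) {
    abort(paste0(
      "summarize_groups(): group(s) with fewer than 2 fitted animals: ",
      paste(small, collapse = ", "),
      ". Mean-rate SE and df are undefined."
    ), class = "tumorgri_insufficient_data_error")
  }
  out
}

# one arm's summary row, with a clear error when the label is absent
group_summary_row <- function(summaries, label, role) {
  row <- summaries[summaries$group == label, ]
  if (nrow(row) != 1) {
    abort(paste0("No arm labelled '", label, "' available for the ", role,
                 " role."),
          class = "tumorgri_validation_error")
  }
  row
}
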