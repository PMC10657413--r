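#' Growth-rate-inhibition percentage (pure formula)
#'
#' `GRI (%) = 100 * (mean control rate - mean treatment rate) / (mean
#' vehicle rate)`. Positive GRI means the treated tumors grew at a reduced
#' rate relative to the reference, expressed as a fraction of the vehicle
#' growth rate.
#'
#' @param mu_treatment,mu_control,mu_vehicle Arm-mean exponential growth
#'   rates (per day). `mu_vehicle` must be nonzero.
#' @return The GRI in percent.
#' @examples
#' gri_percent(0.15, 0.30, 0.30) # 50
#' @export
gri_percent <- function(mu_treatment, mu_control, mu_vehicle) {
  if (any(mu_vehicle == 0)) {
    abort("gri_percent(): vehicle mean growth rate is 0; GRI is undefined.",
          class = "tumorgri_degenerate_error")
  }
  100 * (mu_control - mu_treatment) / mu_vehicle
}

#' Growth-rate synergy score (pure formula)
#'
#' `Synergy score = (mu_AB - mu_A - mu_B + mu_control) / mu_V * 100`, where
#' the mu's are arm-mean exponential growth rates. Zero under exact
#' additivity of rate effects; negative when the combination grows slower
#' than additivity predicts.
#'
#' @param mu_ab,mu_a,mu_b,mu_control Mean growth rates of the combination,
#'   single-agent A, single-agent B, and control arms.
#' @param mu_vehicle Mean growth rate of the vehicle arm (the normalizer;
#'   usually the same as control). Must be nonzero.
#' @return The synergy score in percent.
#' @examples
#' synergy_percent(0.05, 0.2, 0.2, 0.3, 0.3) # -16.67
#' @export
synergy_percent <- function(mu_ab, mu_a, mu_b, mu_control, mu_vehicle) {
  if (any(mu_vehicle == 0)) {
    abort("synergy_percent(): vehicle mean growth rate is 0.",
          class = "tumorgri_degenerate_error")
  }
  100 * (mu_ab - mu_a - mu_b + mu_control) / mu_vehicle
}

#' Welch-Satterthwaite effective degrees of freedom
#'
#' Effective degrees of freedom for a linear combination (unit weights) of
#' independent sample means with unequal variances:
#' `df = (sum se_i^2)^2 / sum(se_i^4 / df_i)`.
#' With two terms this is the familiar Welch two-sample df; with four it is
#' the df of the growth-rate synergy score.
#'
#' @param se Standard errors of the combined means.
#' @param df Per-group degrees of freedom (`n_i - 1`).
#' @return The effective degrees of freedom (a real number).
#' @examples
#' welch_satterthwaite_df(c(0.02, 0.015, 0.015, 0.01), rep(9, 4))
#' @export
welch_satterthwaite_df <- function(se, df) {
  stopifnot(length(se) == length(df))
  if (all(se == 0)) {
    abort("welch_satterthwaite_df(): all standard errors are 0.",
          class = "tumorgri_degenerate_error")
  }
  sum(se^2)^2 / sum(se^4 / df)
}

# Welch test of a unit-weight linear combination of independent group means
# against 0: t = sum(w * means) / sqrt(sum(se^2)), df by Welch-Satterthwaite.
# zero_se = "limit" returns the limiting test (t = 0/Inf, p = 1/0) when all
# group variances vanish, e.g. on noiseless data.
welch_lincomb_test <- function(means, ses, dfs, weights,
                               zero_se = c("error", "limit")) {
  zero_se <- match.arg(zero_se)
  est <- sum(weights * means)
  se <- sqrt(sum(weights^2 * ses^2))
  if (se == 0) {
    if (zero_se == "error") {
      abort("Zero variance across all groups; the t statistic is undefined.",
            class = "tumorgri_degenerate_error")
    }
    t_stat <- if (est == 0) 0 else sign(est) * Inf
    return(list(estimate = est, se = 0, df = NA_real_, t_stat = t_stat,
                p_value = if (est == 0) 1 else 0))
  }
  df <- sum(weights^2 * ses^2)^2 / sum((weights^2 * ses^2)^2 / dfs)
  t_stat <- est / se
  list(estimate = est, se = se, df = df, t_stat = t_stat,
       p_value = 2 * pt(-abs(t_stat), df))
}

#' Welch two-sample test of mean growth rates between two arms
#'
#' Two-sided Welch (unequal-variance) t-test comparing the per-animal
#' exponential growth rates of two arms. This is the significance test
#' behind the GRI: the comparison object is the mean growth rate of each
#' arm, with between-animal variability supplying the error.
#'
#' On degenerate (zero-variance) rate vectors, e.g. noiseless data, the
#' limiting test is returned: `t = 0, p = 1` for equal means and
#' `t = +/-Inf, p = 0` otherwise.
#'
#' @param fits Per-animal fits from [fit_growth()].
#' @param treatment,control Arm labels to compare.
#' @return A one-row tibble: `treatment`, `control`, `estimate` (difference
#'   control - treatment), `t_stat`, `df` (Welch), `p_value` (two-tailed).
#' @export
gri_test <- function(fits, treatment, control) {
  summ <- summarize_groups(
    dplyr::filter(as_tibble(fits), .data$group %in% c(treatment, control))
  )
  s_t <- group_summary_row(summ, treatment, "treatment")
  s_c <- group_summary_row(summ, control, "control")
  res <- welch_lincomb_test(
    means = c(s_c$mean_rate, s_t$mean_rate),
    ses = c(s_c$se, s_t$se),
    dfs = c(s_c$df, s_t$df),
    weights = c(1, -1),
    zero_se = "limit"
  )
  tibble(treatment = treatment, control = control,
         estimate = res$estimate, t_stat = res$t_stat, df = res$df,
         p_value = res$p_value)
}

#' Growth-rate inhibition of a treatment arm
#'
#' Computes the GRI of a treatment arm against a control arm, normalized by
#' the vehicle arm (usually the same as the control), together with a
#' two-sided Welch test on the per-animal growth rates. A positive GRI
#' means the treated tumors grew more slowly than the reference.
#'
#' @param fits Per-animal fits from [fit_growth()]. If the fits came from a
#'   day-restricted window, the GRI is the "GRI on Day `day_hi`" of that
#'   window.
#' @param treatment,control Arm labels.
#' @param vehicle Normalizer arm label; defaults to `control`.
#' @return An object of class `gri_result` with fields `gri_percent`,
#'   `treatment`, `control`, `vehicle`, `t_stat`, `df`, `p_value`,
#'   `day_window`. Use [tidy()] for a one-row tibble.
#' @examples
#' sim <- simulate_cohort(sim_config(
#'   arms = dplyr::bind_rows(
#'     sim_arm("vehicle", n = 8, rate = 0.30),
#'     sim_arm("treated", n = 8, rate = 0.15)
#'   ), seed = 7
#' ))
#' fits <- fit_growth(sim$table)
#' gri(fits, treatment = "treated", control = "vehicle")
#' @export
gri <- function(fits, treatment, control, vehicle = control) {
  fits <- as_tibble(fits)
  summ <- summarize_groups(
    dplyr::filter(fits, .data$group %in% c(treatment, control, vehicle))
  )
  s_t <- group_summary_row(summ, treatment, "treatment")
  s_c <- group_summary_row(summ, control, "control")
  s_v <- group_summary_row(summ, vehicle, "vehicle")
  test <- gri_test(fits, treatment, control)
  window <- if (all(c("day_lo", "day_hi") %in% names(fits))) {
    c(min(fits$day_lo), max(fits$day_hi))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      gri_percent = gri_percent(s_t$mean_rate, s_c$mean_rate, s_v$mean_rate),
      treatment = treatment, control = control, vehicle = vehicle,
      mu_treatment = s_t$mean_rate, mu_control = s_c$mean_rate,
      mu_vehicle = s_v$mean_rate,
      t_stat = test$t_stat, df = test$df, p_value = test$p_value,
      day_window = window
    ),
    class = "gri_result"
  )
}

#' Growth-rate synergy score for a four-arm combination design
#'
#' Scores a combination study with arms control, A, B and A+B on the
#' growth-rate scale: `score = (mu_AB - mu_A - mu_B + mu_control) / mu_V *
#' 100`. The score is 0 under additivity of rate effects; a statistically
#' significant negative score is synergistic.
#'
#' The standard error propagates the four group SEs as the root sum of
#' squares (the variance of a sum of independent means), scaled by
#' `100 / |mu_V|` with the vehicle mean treated as a fixed normalizer
#' (`se_method = "fixed_vehicle"`, the default). `se_method = "delta"` adds
#' a delta-method term for the sampling error of the vehicle denominator
#' (including its covariance with the numerator when the vehicle arm is the
#' control arm). Degrees of freedom come from the Welch-Satterthwaite
#' equation over the four groups; the p-value is two-tailed from the
#' t-distribution of `score / se`.
#'
#' @param fits Per-animal fits from [fit_growth()].
#' @param ab,a,b,control Arm labels for the combination, the two single
#'   agents and the control.
#' @param vehicle Normalizer arm label; defaults to `control`.
#' @param alpha Significance level for the classification, default 0.05.
#' @param se_method `"fixed_vehicle"` (default) or `"delta"`; see Details.
#' @return An object of class `synergy_result` with fields `score_percent`,
#'   `se`, `df`, `t_stat`, `p_value`, `label`, `arms`. Use [tidy()] for a
#'   one-row tibble.
#' @export
synergy_score <- function(fits, ab = "AB", a = "A", b = "B",
                          control = "control", vehicle = control,
                          alpha = 0.05,
                          se_method = c("fixed_vehicle", "delta")) {
  se_method <- match.arg(se_method)
  fits <- as_tibble(fits)
  labels <- c(ab, a, b, control, vehicle)
  summ <- summarize_groups(dplyr::filter(fits, .data$group %in% labels))
  s_ab <- group_summary_row(summ, ab, "combination")
  s_a <- group_summary_row(summ, a, "single-agent A")
  s_b <- group_summary_row(summ, b, "single-agent B")
  s_c <- group_summary_row(summ, control, "control")
  s_v <- group_summary_row(summ, vehicle, "vehicle")
  if (s_v$mean_rate == 0) {
    abort("synergy_score(): vehicle mean growth rate is 0.",
          class = "tumorgri_degenerate_error")
  }

  mu_v <- s_v$mean_rate
  diff <- s_ab$mean_rate - s_a$mean_rate - s_b$mean_rate + s_c$mean_rate
  score <- 100 * diff / mu_v
  ses <- c(s_ab$se, s_a$se, s_b$se, s_c$se)
  dfs <- c(s_ab$df, s_a$df, s_b$df, s_c$df)
  if (all(ses == 0)) {
    abort("synergy_score(): all four group SEs are 0; t is undefined.",
          class = "tumorgri_degenerate_error")
  }
  var_diff <- sum(ses^2)
  if (se_method == "fixed_vehicle") {
    se <- 100 * sqrt(var_diff) / abs(mu_v)
  } else {
    # first-order delta method for diff / mu_v; cov(diff, mu_v) = +se_c^2
    # when the vehicle arm is the control arm (control enters diff with +1)
    cov_dv <- if (identical(vehicle, control)) s_c$se^2 else 0
    var_ratio <- var_diff / mu_v^2 + diff^2 * s_v$se^2 / mu_v^4 -
      2 * diff * cov_dv / mu_v^3
    se <- 100 * sqrt(max(var_ratio, 0))
  }
  df <- welch_satterthwaite_df(ses, dfs)
  t_stat <- score / se
  p_value <- 2 * pt(-abs(t_stat), df)
  label <- classify_combination(score, p_value, s_ab$mean_rate,
                                s_a$mean_rate, s_b$mean_rate, alpha = alpha)
  structure(
    list(
      score_percent = score, se = se, df = df, t_stat = t_stat,
      p_value = p_value, label = label,
      arms = c(ab = ab, a = a, b = b, control = control, vehicle = vehicle),
      mu = c(ab = s_ab$mean_rate, a = s_a$mean_rate, b = s_b$mean_rate,
             control = s_c$mean_rate, vehicle = mu_v),
      alpha = alpha, se_method = se_method
    ),
    class = "synergy_result"
  )
}

#' Classify a combination from its synergy score
#'
#' Deterministic, exhaustive classification of a growth-rate synergy score:
#' not significant at `alpha` is `additive`; a significant negative score is
#' `synergistic`; a significant positive score is `sub-additive` when the
#' combination still beats the best single agent (lower mean growth rate),
#' and `antagonistic` otherwise.
#'
#' @param score_percent Synergy score in percent.
#' @param p_value Two-tailed p-value of the score.
#' @param mu_ab,mu_a,mu_b Mean growth rates of the combination and the two
#'   single-agent arms.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return One of `"synergistic"`, `"additive"`, `"sub-additive"`,
#'   `"antagonistic"`.
#' @export
classify_combination <- function(score_percent, p_value, mu_ab, mu_a, mu_b,
                                 alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.na(p_value) || p_value >= alpha || score_percent == 0) {
    return("additive")
  }
  if (score_percent < 0) {
    return("synergistic")
  }
  if (mu_ab < min(mu_a, mu_b)) "sub-additive" else "antagonistic"
}

#' Treated-over-control mean tumor volume ratio at a fixed day
#'
#' The classical T/C endpoint: `100 * mean(treatment volumes at day) /
#' mean(control volumes at day)`, using animals measured on that exact
#' study day.
#'
#' @param data A measurement table.
#' @param treatment,control Arm labels.
#' @param day Study day at which to compare.
#' @return A one-row tibble: `treatment`, `control`, `day`, `n_treatment`,
#'   `n_control`, `tc_percent`.
#' @export
tc_ratio <- function(data, treatment, control, day) {
  tbl <- as_tibble(data)
  at_day <- function(grp) {
    v <- tbl$volume[tbl$group == grp & tbl$day == day & !is.na(tbl$volume)]
    if (length(v) == 0) {
      abort(paste0("tc_ratio(): no volumes at day ", day, " in arm '",
                   grp, "'."),
            class = "tumorgri_missing_day_error")
    }
    v
  }
  vt <- at_day(treatment)
  vc <- at_day(control)
  if (mean(vc) == 0) {
    abort("tc_ratio(): control mean volume is 0 at the requested day.",
          class = "tumorgri_degenerate_error")
  }
  tibble(treatment = treatment, control = control, day = day,
         n_treatment = length(vt), n_control = length(vc),
         tc_percent = 100 * mean(vt) / mean(vc))
}

#' Per-arm mean percent body-weight change by day
#'
#' For each animal, percent change versus its pre-dose Day-0 body weight;
#' for each arm and day, the mean of those per-animal changes. Negative
#' values are losses.
#'
#' @param data A measurement table with `body_weight` recorded; every
#'   animal must have a Day-0 weight.
#' @return A tibble: `group`, `day`, `mean_pct_change`, `n`.
#' @seealso [max_body_weight_loss()] for the worst arm-mean loss.
#' @export
body_weight_loss <- function(data) {
  tbl <- dplyr::filter(as_tibble(data), !is.na(.data$body_weight))
  base <- tbl %>%
    dplyr::filter(.data$day == 0) %>%
    dplyr::select("animal_id", w0 = "body_weight")
  missing <- setdiff(unique(as_tibble(data)$animal_id), base$animal_id)
  if (length(missing) > 0) {
    abort(paste0("body_weight_loss(): animal(s) missing a Day-0 body ",
                 "weight: ", paste(sort(missing), collapse = ", ")),
          class = "tumorgri_validation_error")
  }
  tbl %>%
    dplyr::inner_join(base, by = "animal_id") %>%
    dplyr::mutate(pct_change = 100 * (.data$body_weight - .data$w0) / .data$w0) %>%
    dplyr::group_by(.data$group, .data$day) %>%
    dplyr::summarise(mean_pct_change = mean(.data$pct_change),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$group, .data$day)
}

#' Maximal mean percent body-weight loss per arm
#'
#' The worst (most negative) arm-mean percent body-weight change over the
#' treatment period, reported as a positive loss magnitude with the day it
#' occurred. Arms that never lose weight on average report 0 with `max_day
#' = NA`.
#'
#' @inheritParams body_weight_loss
#' @return A tibble: `group`, `max_mean_bwl_percent`, `max_day`.
#' @export
max_body_weight_loss <- function(data) {
  body_weight_loss(data) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      max_mean_bwl_percent = max(0, -min(.data$mean_pct_change)),
      max_day = if (min(.data$mean_pct_change) < 0) {
        .data$day[which.min(.data$mean_pct_change)]
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Complete responders per arm
#'
#' Counts animals whose tumor became unpalpable (recorded volume exactly 0
#' mm^3). Under the default `"sustained"` policy an animal is a complete
#' responder iff its final recorded volume is 0 and every measurement after
#' first reaching 0 stayed at 0 (no regrowth). The `"final"` policy only
#' requires a 0 at the final assessment.
#'
#' @param data A measurement table.
#' @param policy `"sustained"` (default) or `"final"`.
#' @return A tibble: `group`, `n`, `cr_count`, `cr_animals` (list column of
#'   animal ids).
#' @export
complete_responders <- function(data, policy = c("sustained", "final")) {
  policy <- match.arg(policy)
  tbl <- as_tibble(data) %>%
    dplyr::filter(!is.na(.data$volume)) %>%
    dplyr::arrange(.data$animal_id, .data$day)
  per_animal <- tbl %>%
    dplyr::group_by(.data$animal_id, .data$group) %>%
    dplyr::summarise(
      final_zero = dplyr::last(.data$volume) == 0,
      sustained = any(.data$volume == 0) &&
        all(.data$volume[seq_along(.data$volume) >=
                           which(.data$volume == 0)[1]] == 0),
      .groups = "drop"
    ) %>%
    dplyr::mutate(cr = if (policy == "sustained") {
      .data$sustained
    } else {
      .data$final_zero
    })
  per_animal %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      cr_count = sum(.data$cr),
      cr_animals = list(.data$animal_id[.data$cr]),
      .groups = "drop"
    )
}
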