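#' Specify one arm of a synthetic study
#'
#' @param label Arm label.
#' @param n Animals in the arm (>= 2).
#' @param rate True mean exponential growth rate, per day.
#' @param rate_sd Between-animal SD of the true growth rate, per day.
#'   Default 0.03, a realistic heterogeneity for syngeneic flank tumors.
#' @param p_cr Probability an animal is a complete responder (switches to a
#'   regressing rate at `cr_onset_day`).
#' @param cr_rate Regression rate (per day, negative) a responder follows
#'   after onset. Default -0.25.
#' @param cr_onset_day Day a responder's regression starts. Default 7.
#' @param bwl_rate Fractional body-weight change per day (negative =
#'   loss); 0 keeps weights constant at 20 g.
#' @return A one-row tibble describing the arm.
#' @export
sim_arm <- function(label, n = 10, rate = 0.25, rate_sd = 0.03, p_cr = 0,
                    cr_rate = -0.25, cr_onset_day = 7, bwl_rate = 0) {
  tibble(label = label, n = n, rate = rate, rate_sd = rate_sd, p_cr = p_cr,
         cr_rate = cr_rate, cr_onset_day = cr_onset_day,
         bwl_rate = bwl_rate)
}

#' Configure a synthetic syngeneic study
#'
#' Bundles the full parameterization of a simulated caliper study:
#' randomization near a 30 mm^3 mean tumor volume, arm-specific mean growth
#' rates with between-animal heterogeneity, multiplicative lognormal
#' measurement noise, a thrice-weekly measurement schedule, a
#' complete-response process, a detection floor below which volumes record
#' as 0, and humane-endpoint removal driven by the latent (noise-free)
#' volume.
#'
#' @param arms A tibble of arm specs, one row per arm (see [sim_arm()]).
#' @param seed RNG seed; together with the config it fully determines the
#'   simulated study.
#' @param baseline_mtv Mean enrollment tumor volume, mm^3. Default 30.
#' @param baseline_cv Coefficient of variation of starting volumes.
#'   Default 0.3.
#' @param noise_sd SD of the multiplicative lognormal measurement noise on
#'   the log scale (or, for `noise_model = "additive"`, the absolute SD in
#'   mm^3). Default 0.1.
#' @param schedule Measurement days; `NULL` gives the thrice-weekly
#'   pattern 0, 2, 4, 7, 9, 11, ... up to `study_end_day`.
#' @param study_end_day Last scheduled day. Default 74.
#' @param endpoint_volume Surrogate-mortality threshold, mm^3. Default 1200.
#' @param humane_removal_volume Latent volume at which an animal is removed
#'   (measured that day, then no further rows), mm^3. Default 2000; must be
#'   >= `endpoint_volume`.
#' @param detection_floor Volume below which a measurement records 0 (no
#'   palpable tumor), mm^3. Default 5.
#' @param noise_model `"lognormal"` (default; the fitting model is then
#'   correctly specified) or `"additive"` (Gaussian noise on the volume
#'   scale, a deliberate misspecification scenario).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(arms, seed = 1, baseline_mtv = 30, baseline_cv = 0.3,
                       noise_sd = 0.1, schedule = NULL, study_end_day = 74,
                       endpoint_volume = 1200,
                       humane_removal_volume = 2000, detection_floor = 5,
                       noise_model = c("lognormal", "additive")) {
  noise_model <- match.arg(noise_model)
  if (is.null(schedule)) {
    schedule <- thrice_weekly_schedule(study_end_day)
  }
  cfg <- structure(
    list(arms = as_tibble(arms), seed = seed, baseline_mtv = baseline_mtv,
         baseline_cv = baseline_cv, noise_sd = noise_sd,
         schedule = sort(unique(schedule)), study_end_day = study_end_day,
         endpoint_volume = endpoint_volume,
         humane_removal_volume = humane_removal_volume,
         detection_floor = detection_floor, noise_model = noise_model),
    class = "sim_config"
  )
  problems <- validate_sim_config(cfg)
  if (length(problems) > 0) {
    abort(paste0("Invalid simulation config:\n",
                 paste0("- ", problems, collapse = "\n")),
          class = "tumorgri_config_error")
  }
  cfg
}

# Mon/Wed/Fri-like measurement grid: 0, 2, 4 within each week
thrice_weekly_schedule <- function(end_day) {
  weeks <- 7 * (0:(end_day %/% 7))
  days <- sort(unique(as.vector(outer(c(0, 2, 4), weeks, `+`))))
  days[days <= end_day]
}

validate_sim_config <- function(cfg) {
  p <- character()
  a <- cfg$arms
  req <- c("label", "n", "rate", "rate_sd", "p_cr", "cr_rate",
           "cr_onset_day", "bwl_rate")
  if (!all(req %in% names(a))) {
    return(paste0("arms must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(a) < 1) p <- c(p, "at least one arm is required")
  if (anyDuplicated(a$label)) p <- c(p, "arm labels must be unique")
  if (any(a$n < 2)) p <- c(p, "every arm needs n >= 2")
  if (any(a$rate_sd < 0)) p <- c(p, "rate_sd must be >= 0")
  if (any(a$p_cr < 0 | a$p_cr > 1)) p <- c(p, "p_cr must lie in [0, 1]")
  if (cfg$noise_sd < 0) p <- c(p, "noise_sd must be >= 0")
  if (cfg$baseline_mtv <= 0) p <- c(p, "baseline_mtv must be > 0")
  if (cfg$baseline_cv < 0) p <- c(p, "baseline_cv must be >= 0")
  if (cfg$detection_floor < 0) p <- c(p, "detection_floor must be >= 0")
  if (cfg$endpoint_volume > cfg$humane_removal_volume) {
    p <- c(p, "endpoint_volume must be <= humane_removal_volume")
  }
  if (length(cfg$schedule) < 2) p <- c(p, "schedule needs >= 2 days")
  if (any(cfg$schedule < 0)) p <- c(p, "schedule days must be >= 0")
  p
}

#' Simulate a synthetic caliper study with known ground truth
#'
#' Generates a full measurement table plus the per-animal truth behind it.
#' Per animal: a lognormal starting volume centered on `baseline_mtv`, a
#' Normal true growth rate around the arm mean, and (with probability
#' `p_cr`) a complete-response switch to `cr_rate` at `cr_onset_day`.
#' Observed volumes are the latent exponential trajectory times lognormal
#' measurement noise, recorded as 0 below the detection floor. An animal is
#' measured on the schedule through the first day its latent volume reaches
#' `humane_removal_volume`, then contributes no further rows (informative
#' dropout). Body weights are constant 20 g unless an arm sets `bwl_rate`.
#' The same seed and config always reproduce the identical study.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_study`: `table` (measurement tibble),
#'   `truth` (per-animal `true_rate`, `cr`, `v0`, `removal_day`), `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(
#'   arms = sim_arm("vehicle", n = 5, rate = 0.3), seed = 42,
#'   study_end_day = 21
#' ))
#' head(sim$table)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  arms <- cfg$arms
  animals <- tidyr::uncount(arms, weights = .data$n, .id = "idx") %>%
    dplyr::mutate(animal_id = sprintf("%s-%02d", .data$label, .data$idx))
  n_animals <- nrow(animals)

  sdlog <- sqrt(log(1 + cfg$baseline_cv^2))
  meanlog <- log(cfg$baseline_mtv) - sdlog^2 / 2
  animals$v0 <- rlnorm(n_animals, meanlog, sdlog)
  animals$true_rate <- rnorm(n_animals, animals$rate, animals$rate_sd)
  animals$cr <- rbinom(n_animals, 1, animals$p_cr) == 1

  grid <- tidyr::crossing(
    dplyr::select(animals, "animal_id", group = "label", "v0", "true_rate",
                  "cr", "cr_rate", "cr_onset_day", "bwl_rate"),
    day = cfg$schedule
  ) %>%
    dplyr::arrange(.data$animal_id, .data$day) %>%
    dplyr::mutate(
      latent_log = log(.data$v0) +
        dplyr::if_else(
          .data$cr,
          .data$true_rate * pmin(.data$day, .data$cr_onset_day) +
            .data$cr_rate * pmax(.data$day - .data$cr_onset_day, 0),
          .data$true_rate * .data$day
        ),
      latent = exp(.data$latent_log)
    )

  # fixed draw order keeps the study reproducible regardless of dropout
  eps <- rnorm(nrow(grid), 0, cfg$noise_sd)
  grid$observed <- if (cfg$noise_model == "lognormal") {
    grid$latent * exp(eps)
  } else {
    pmax(grid$latent + eps, 0)
  }
  grid$observed[grid$observed < cfg$detection_floor] <- 0

  # removal keys on the latent volume: measured on the removal day, gone after
  grid <- grid %>%
    dplyr::group_by(.data$animal_id) %>%
    dplyr::mutate(
      removal_day = if (any(.data$latent >= cfg$humane_removal_volume)) {
        .data$day[which(.data$latent >= cfg$humane_removal_volume)[1]]
      } else {
        NA_real_
      }
    ) %>%
    dplyr::ungroup() %>%
    dplyr::filter(is.na(.data$removal_day) | .data$day <= .data$removal_day)

  table <- grid %>%
    dplyr::mutate(
      body_weight = 20 * (1 + .data$bwl_rate * .data$day),
      length = NA_real_, width = NA_real_
    ) %>%
    dplyr::select("animal_id", "group", "day", "length", "width",
                  volume = "observed", "body_weight")

  truth <- grid %>%
    dplyr::distinct(.data$animal_id, group = .data$group, .data$v0,
                    .data$true_rate, .data$cr, .data$removal_day)

  structure(list(table = table, truth = truth, config = cfg),
            class = "simulated_study")
}

#' Simulate a four-arm study under the exact additive null
#'
#' For arms labelled `control`, `A`, `B` and `AB`, overrides the `AB` arm's
#' true mean growth rate with `rate_A + rate_B - rate_control` before
#' sampling, so the true growth-rate synergy score is exactly 0. Everything
#' else behaves as [simulate_cohort()]. This is the null instrument for
#' type-I-error studies of the synergy test.
#'
#' @param config A [sim_config()] whose arms are exactly
#'   `control`, `A`, `B`, `AB` (any order).
#' @return A `simulated_study` (see [simulate_cohort()]); the config inside
#'   carries the overridden `AB` rate.
#' @export
simulate_additive_null <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labs <- config$arms$label
  if (!setequal(labs, c("control", "A", "B", "AB"))) {
    abort(paste0("simulate_additive_null(): arms must be exactly ",
                 "{control, A, B, AB}; got {",
                 paste(labs, collapse = ", "), "}."),
          class = "tumorgri_config_error")
  }
  rate_of <- function(l) config$arms$rate[config$arms$label == l]
  config$arms$rate[config$arms$label == "AB"] <-
    rate_of("A") + rate_of("B") - rate_of("control")
  simulate_cohort(config)
}

#' Monte-Carlo operating characteristics of the pipeline
#'
#' Repeats a simulated study `n_reps` times (replicate `k` uses seed
#' `config$seed + k`), runs the fitting and efficacy stages on each
#' replicate, and summarizes how well the pipeline recovers the configured
#' truth: per-arm mean-rate bias and RMSE, GRI bias and RMSE for each
#' non-control arm (control = vehicle = the first arm), mean
#' complete-responder counts, and — for four-arm `control/A/B/AB` designs —
#' the rejection rate of the synergy t-test at `alpha`. Every estimate
#' carries its Monte-Carlo standard error.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicate studies (>= 100).
#' @param alpha Significance level for the synergy test. Default 0.05.
#' @param additive_null If `TRUE`, each replicate is drawn with
#'   [simulate_additive_null()] (requires `control/A/B/AB` arms), making
#'   the true synergy score exactly 0.
#' @param control Label of the arm used as control and vehicle for GRI.
#'   Default `"control"` if present, else the first arm.
#' @param fit_floor Volume floor passed to [fit_growth()]. Default 1.
#' @return A tibble with columns `metric`, `arm`, `truth`, `estimate`,
#'   `mc_se`, `rmse`, `n_reps`.
#' @export
run_operating_characteristics <- function(config, n_reps, alpha = 0.05,
                                          additive_null = FALSE,
                                          control = NULL, fit_floor = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 100) {
    abort("run_operating_characteristics(): n_reps must be >= 100.",
          class = "tumorgri_validation_error")
  }
  labs <- config$arms$label
  four_arm <- setequal(labs, c("control", "A", "B", "AB"))
  if (additive_null && !four_arm) {
    abort("additive_null = TRUE requires arms {control, A, B, AB}.",
          class = "tumorgri_config_error")
  }
  if (is.null(control)) {
    control <- if ("control" %in% labs) "control" else labs[1]
  }
  trt_arms <- setdiff(labs, control)

  true_rates <- setNames(config$arms$rate, config$arms$label)
  if (additive_null) {
    true_rates[["AB"]] <-
      true_rates[["A"]] + true_rates[["B"]] - true_rates[["control"]]
  }
  true_gri <- setNames(
    100 * (true_rates[control] - true_rates[trt_arms]) / true_rates[control],
    trt_arms
  )
  true_score <- if (four_arm) {
    100 * (true_rates[["AB"]] - true_rates[["A"]] - true_rates[["B"]] +
             true_rates[["control"]]) / true_rates[[control]]
  } else {
    NA_real_
  }

  one_rep <- function(k) {
    cfg <- config
    # prime stride keeps replicate streams disjoint across nearby base seeds
    cfg$seed <- config$seed + k * 1009
    sim <- if (additive_null) simulate_additive_null(cfg) else
      simulate_cohort(cfg)
    fits <- suppressWarnings(fit_growth(sim$table, floor = fit_floor))
    summ <- summarize_groups(fits)
    mu <- setNames(summ$mean_rate, summ$group)
    gris <- setNames(100 * (mu[control] - mu[trt_arms]) / mu[control],
                     trt_arms)
    syn_p <- NA_real_
    syn_score <- NA_real_
    if (four_arm) {
      syn <- synergy_score(fits, ab = "AB", a = "A", b = "B",
                           control = "control", vehicle = control,
                           alpha = alpha)
      syn_p <- syn$p_value
      syn_score <- syn$score_percent
    }
    crs <- complete_responders(sim$table)
    list(mu = mu, gri = gris, syn_p = syn_p, syn_score = syn_score,
         cr = setNames(crs$cr_count, crs$group))
  }

  reps <- lapply(seq_len(n_reps), one_rep)
  mc <- function(x) sd(x) / sqrt(length(x))
  rows <- list()
  for (arm in labs) {
    est <- vapply(reps, function(r) r$mu[[arm]], numeric(1))
    rows <- c(rows, list(tibble(
      metric = "mean_rate", arm = arm, truth = true_rates[[arm]],
      estimate = mean(est), mc_se = mc(est),
      rmse = sqrt(mean((est - true_rates[[arm]])^2)), n_reps = n_reps
    )))
    cr <- vapply(reps, function(r) {
      if (arm %in% names(r$cr)) r$cr[[arm]] else 0
    }, numeric(1))
    rows <- c(rows, list(tibble(
      metric = "cr_count", arm = arm, truth = NA_real_,
      estimate = mean(cr), mc_se = mc(cr), rmse = NA_real_, n_reps = n_reps
    )))
  }
  for (arm in trt_arms) {
    est <- vapply(reps, function(r) r$gri[[arm]], numeric(1))
    rows <- c(rows, list(tibble(
      metric = "gri", arm = arm, truth = unname(true_gri[arm]),
      estimate = mean(est), mc_se = mc(est),
      rmse = sqrt(mean((est - true_gri[arm])^2)), n_reps = n_reps
    )))
  }
  if (four_arm) {
    ps <- vapply(reps, function(r) r$syn_p, numeric(1))
    scores <- vapply(reps, function(r) r$syn_score, numeric(1))
    rej <- mean(ps < alpha)
    rows <- c(rows, list(
      tibble(metric = "synergy_rejection_rate", arm = "AB",
             truth = if (additive_null) alpha else NA_real_,
             estimate = rej, mc_se = sqrt(rej * (1 - rej) / n_reps),
             rmse = NA_real_, n_reps = n_reps),
      tibble(metric = "synergy_score", arm = "AB", truth = unname(true_score),
             estimate = mean(scores), mc_se = mc(scores),
             rmse = sqrt(mean((scores - true_score)^2)), n_reps = n_reps)
    ))
  }
  dplyr::bind_rows(rows)
}
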