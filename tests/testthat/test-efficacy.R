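test_that("GRI formula spot values", {
  expect_equal(gri_percent(0.15, 0.30, 0.30), 50)
  expect_equal(gri_percent(0.30, 0.30, 0.30), 0)
  expect_equal(gri_percent(0.00, 0.30, 0.30), 100)
  expect_error(gri_percent(0.1, 0.2, 0), class = "tumorgri_degenerate_error")
})

test_that("GRI is antisymmetric and invariant to time-unit rescaling", {
  set.seed(33)
  mt <- runif(1, 0.05, 0.2); mc <- runif(1, 0.2, 0.4)
  expect_equal(gri_percent(mt, mc, mc), -gri_percent(mc, mt, mc))
  for (k in c(0.5, 24)) {
    expect_equal(gri_percent(mt * k, mc * k, mc * k), gri_percent(mt, mc, mc))
  }
})

test_that("the Welch rate test matches hand formulas and t.test", {
  a <- c(0.30, 0.31, 0.29)
  b <- c(0.10, 0.11, 0.09)
  fits <- fits_from_rates(control = a, treated = b)
  res <- gri_test(fits, treatment = "treated", control = "control")
  # independent closed-form Welch evaluation
  va <- var(a) / 3; vb <- var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # frozen values and a library cross-check
  expect_equal(res$t_stat, 24.4948974278, tolerance = 1e-8)
  expect_equal(res$df, 4)
  tt <- t.test(a, b)
  expect_equal(res$p_value, unname(tt$p.value), tolerance = 1e-12)
})

test_that("identical arms give t = 0, p = 1; singleton arms error", {
  fits <- fits_from_rates(x = c(0.1, 0.2, 0.3), y = c(0.1, 0.2, 0.3))
  res <- gri_test(fits, "x", "y")
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_error(gri_test(fits_from_rates(x = c(0.1, 0.2), y = 0.3), "x", "y"),
               class = "tumorgri_insufficient_data_error")
})

test_that("gri() combines the formula and the Welch test", {
  fits <- fits_from_rates(
    vehicle = c(0.29, 0.30, 0.31),
    treated = c(0.14, 0.15, 0.16)
  )
  g <- gri(fits, treatment = "treated", control = "vehicle")
  expect_s3_class(g, "gri_result")
  expect_equal(g$gri_percent, 50)
  td <- tidy(g)
  expect_equal(td$gri_percent, 50)
  expect_equal(td$p_value, gri_test(fits, "treated", "vehicle")$p_value)
})

test_that("synergy formula spot values", {
  expect_equal(synergy_percent(0.05, 0.2, 0.2, 0.3, 0.3), -50 / 3,
               tolerance = 1e-12)
  # exact additivity gives 0 whatever the normalizer
  expect_equal(synergy_percent(0.12, 0.2, 0.22, 0.3, 0.25), 0)
  expect_error(synergy_percent(0.1, 0.2, 0.2, 0.3, 0),
               class = "tumorgri_degenerate_error")
})

test_that("Welch-Satterthwaite df matches the hand-evaluated expression", {
  se <- c(0.02, 0.015, 0.015, 0.01)
  expect_equal(welch_satterthwaite_df(se, rep(9, 4)),
               sum(se^2)^2 / sum(se^4 / 9), tolerance = 1e-12)
  expect_equal(welch_satterthwaite_df(se, rep(9, 4)), 29.9447004608,
               tolerance = 1e-8)
  # reduces to the two-sample Welch df when two of four SEs vanish
  expect_equal(
    welch_satterthwaite_df(c(0.02, 0, 0, 0.01), c(9, 9, 9, 9)),
    (0.02^2 + 0.01^2)^2 / (0.02^4 / 9 + 0.01^4 / 9),
    tolerance = 1e-12
  )
})

test_that("synergy score: value, SE propagation, df, and p", {
  base <- c(-0.02, -0.01, 0, 0.01, 0.02)
  fits <- fits_from_rates(
    AB = 0.10 + base, A = 0.20 + base, B = 0.22 + base,
    control = 0.30 + base
  )
  syn <- synergy_score(fits)
  summ <- summarize_groups(fits)
  mu <- setNames(summ$mean_rate, summ$group)
  se_g <- setNames(summ$se, summ$group)
  expect_equal(syn$score_percent,
               100 * (mu["AB"] - mu["A"] - mu["B"] + mu["control"]) /
                 mu["control"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(syn$se,
               100 * sqrt(sum(se_g^2)) / abs(mu["control"]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(syn$df, sum(se_g^2)^2 / sum(se_g^4 / 4), tolerance = 1e-12)
  expect_equal(syn$t_stat, syn$score_percent / syn$se, tolerance = 1e-12)
  expect_equal(syn$p_value, 2 * pt(-abs(syn$t_stat), syn$df),
               tolerance = 1e-12)
})

test_that("synergy score is 0 under exact additivity, for any spread", {
  set.seed(44)
  for (i in 1:10) {
    spread_a <- rnorm(6, 0, 0.02); spread_a <- spread_a - mean(spread_a)
    spread_b <- rnorm(6, 0, 0.05); spread_b <- spread_b - mean(spread_b)
    mu_a <- 0.2; mu_b <- 0.25; mu_c <- 0.3
    fits <- fits_from_rates(
      AB = (mu_a + mu_b - mu_c) + spread_a,
      A = mu_a + spread_b, B = mu_b + spread_a, control = mu_c + spread_b
    )
    expect_equal(synergy_score(fits)$score_percent, 0, tolerance = 1e-9)
  }
})

test_that("synergy score is linear in mu_AB with slope 100 / mu_V", {
  base <- c(-0.01, 0, 0.01)
  make <- function(shift) {
    synergy_score(fits_from_rates(
      AB = 0.10 + shift + base, A = 0.2 + base, B = 0.22 + base,
      control = 0.3 + base
    ))$score_percent
  }
  s0 <- make(0)
  for (d in c(0.01, 0.05, -0.02)) {
    expect_equal(make(d) - s0, 100 * d / 0.3, tolerance = 1e-9)
  }
})

test_that("synergy df respects its bounds on random group configurations", {
  set.seed(55)
  for (i in 1:25) {
    ns <- sample(3:12, 4, replace = TRUE)
    fits <- fits_from_rates(
      AB = rnorm(ns[1], 0.1, 0.03), A = rnorm(ns[2], 0.2, 0.01),
      B = rnorm(ns[3], 0.22, 0.05), control = rnorm(ns[4], 0.3, 0.02)
    )
    syn <- synergy_score(fits)
    expect_gte(syn$df, min(ns - 1) - 1e-9)
    expect_lte(syn$df, sum(ns - 1) + 1e-9)
  }
})

test_that("degenerate synergy inputs error", {
  base <- c(-0.01, 0, 0.01)
  # vehicle mean rate 0
  fits0 <- fits_from_rates(AB = 0.1 + base, A = 0.2 + base, B = 0.2 + base,
                           control = 0 + base)
  expect_error(synergy_score(fits0), class = "tumorgri_degenerate_error")
  # all four groups with zero spread
  fitsz <- fits_from_rates(AB = rep(0.1, 3), A = rep(0.2, 3),
                           B = rep(0.2, 3), control = rep(0.3, 3))
  expect_error(synergy_score(fitsz), class = "tumorgri_degenerate_error")
})

test_that("delta-method SE exceeds the fixed-vehicle SE away from the null", {
  base <- c(-0.02, -0.01, 0, 0.01, 0.02)
  fits <- fits_from_rates(
    AB = 0.05 + base, A = 0.2 + base, B = 0.22 + base, control = 0.3 + base
  )
  fixed <- synergy_score(fits, se_method = "fixed_vehicle")
  delta <- synergy_score(fits, se_method = "delta")
  expect_equal(fixed$score_percent, delta$score_percent)
  expect_false(isTRUE(all.equal(fixed$se, delta$se)))
})

test_that("combination classification follows the label rules exhaustively", {
  expect_equal(classify_combination(-20, 0.01, 0.1, 0.2, 0.25), "synergistic")
  expect_equal(classify_combination(15, 0.40, 0.1, 0.2, 0.25), "additive")
  expect_equal(classify_combination(15, 0.01, 0.10, 0.20, 0.25),
               "sub-additive")
  expect_equal(classify_combination(15, 0.01, 0.22, 0.20, 0.25),
               "antagonistic")
  # every random input yields exactly one of the four labels
  set.seed(66)
  for (i in 1:50) {
    lab <- classify_combination(rnorm(1, 0, 20), runif(1), runif(1, 0, 0.3),
                                runif(1, 0, 0.3), runif(1, 0, 0.3))
    expect_true(lab %in% c("synergistic", "additive", "sub-additive",
                           "antagonistic"))
  }
})

test_that("T/C ratio compares arm mean volumes at a fixed day", {
  tbl <- tibble::tibble(
    animal_id = c("t1", "t2", "c1", "c2"),
    group = c("trt", "trt", "ctl", "ctl"),
    day = 5,
    volume = c(100, 100, 200, 200)
  )
  expect_equal(tc_ratio(tbl, "trt", "ctl", 5)$tc_percent, 50)
  eq <- dplyr::mutate(tbl, volume = 150)
  expect_equal(tc_ratio(eq, "trt", "ctl", 5)$tc_percent, 100)
  expect_error(tc_ratio(tbl, "trt", "ctl", 9),
               class = "tumorgri_missing_day_error")
  zero <- dplyr::mutate(tbl, volume = c(100, 100, 0, 0))
  expect_error(tc_ratio(zero, "trt", "ctl", 5),
               class = "tumorgri_degenerate_error")
})

test_that("body-weight loss is the mean percent change versus Day 0", {
  tbl <- tibble::tibble(
    animal_id = rep(c("m1", "m2"), each = 2),
    group = "trt",
    day = rep(c(0, 3), 2),
    volume = 100,
    body_weight = c(20, 19, 20, 20)
  )
  bwl <- body_weight_loss(tbl)
  expect_equal(bwl$mean_pct_change[bwl$day == 0], 0)
  expect_equal(bwl$mean_pct_change[bwl$day == 3], -2.5)
  mx <- max_body_weight_loss(tbl)
  expect_equal(mx$max_mean_bwl_percent, 2.5)
  expect_equal(mx$max_day, 3)

  flat <- dplyr::mutate(tbl, body_weight = 20)
  mx0 <- max_body_weight_loss(flat)
  expect_equal(mx0$max_mean_bwl_percent, 0)
  expect_true(is.na(mx0$max_day))

  no_base <- tbl[tbl$day != 0 | tbl$animal_id != "m2", ]
  no_base$body_weight[no_base$animal_id == "m2"] <- NA
  expect_error(body_weight_loss(no_base), regexp = "m2",
               class = "tumorgri_validation_error")
})

test_that("complete responders follow the no-regrowth policy", {
  tbl <- tibble::tibble(
    animal_id = rep(c("m1", "m2", "m3"), each = 4),
    group = "trt",
    day = rep(c(0, 10, 30, 40), 3),
    volume = c(
      100, 150, 200, 250,  # never regresses
      100, 20, 0, 0,       # sustained CR from day 30
      100, 20, 0, 150      # regrowth after touching 0
    )
  )
  cr <- complete_responders(tbl)
  expect_equal(cr$n, 3)
  expect_equal(cr$cr_count, 1)
  expect_equal(cr$cr_animals[[1]], "m2")
  # the final-day policy also accepts animals that end at 0 after regrowth
  tbl2 <- tbl
  tbl2$volume[9:12] <- c(100, 0, 150, 0)
  expect_equal(complete_responders(tbl2, policy = "sustained")$cr_count, 1)
  expect_equal(complete_responders(tbl2, policy = "final")$cr_count, 2)
})
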