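test_that("surrogate events use the first crossing of the endpoint volume", {
  tbl <- tibble::tibble(
    animal_id = rep(c("m1", "m2", "m3"), times = c(2, 3, 2)),
    group = "g",
    day = c(7, 9, 7, 20, 46, 9, 12),
    volume = c(800, 1300, 100, 400, 900, 1250, 900)
  )
  ev <- surrogate_events(tbl, threshold = 1200)
  expect_equal(ev$time[ev$animal_id == "m1"], 9)
  expect_equal(ev$event[ev$animal_id == "m1"], 1L)
  # never crosses: censored at the last measured day
  expect_equal(ev$time[ev$animal_id == "m2"], 46)
  expect_equal(ev$event[ev$animal_id == "m2"], 0L)
  # crosses then regresses: still an event at the first crossing
  expect_equal(ev$time[ev$animal_id == "m3"], 9)
  expect_equal(ev$event[ev$animal_id == "m3"], 1L)
})

test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  rec <- tibble::tibble(animal_id = c("a", "b"), group = "g",
                        time = c(5, 10), event = 1L)
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 5], 0.5)
  expect_equal(km$survival[km$time == 10], 0)

  # shrinking risk set: events at 5, 8; censored at 6, 20
  rec2 <- tibble::tibble(animal_id = letters[1:4], group = "g",
                         time = c(5, 8, 6, 20), event = c(1L, 1L, 0L, 0L))
  km2 <- km_estimate(rec2)
  expect_equal(km2$survival[km2$time == 5], 0.75)
  expect_equal(km2$survival[km2$time == 8], 0.375)

  allc <- tibble::tibble(animal_id = letters[1:3], group = "g",
                         time = c(4, 9, 12), event = 0L)
  expect_true(all(km_estimate(allc)$survival == 1))
  expect_error(km_estimate(allc[0, ]), class = "tumorgri_validation_error")
})

test_that("KM curves match the brute-force product-limit oracle", {
  set.seed(88)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    rec <- tibble::tibble(
      animal_id = paste0("m", seq_len(n)), group = "g",
      time = sample(1:15, n, replace = TRUE),
      event = rbinom(n, 1, 0.7)
    )
    km <- km_estimate(rec)
    oracle <- brute_km(rec$time, rec$event)
    merged <- merge(as.data.frame(km), oracle, by = "time",
                    suffixes = c("", "_oracle"))
    expect_equal(merged$survival, merged$survival_oracle, tolerance = 1e-12)
    expect_equal(merged$n_risk, merged$n_risk_oracle)
  }
})

test_that("KM survival is monotone in [0, 1] and censoring-closed", {
  set.seed(89)
  rec <- tibble::tibble(
    animal_id = paste0("m", 1:10), group = "g",
    time = sample(1:20, 10, replace = TRUE), event = rbinom(10, 1, 0.5)
  )
  km <- km_estimate(rec)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  # moving a censoring time within an inter-event gap leaves every
  # event-time survival value unchanged (risk sets at events are identical)
  ev_times <- sort(km$time[km$n_event > 0])
  cens_idx <- which(rec$event == 0 &
                      rec$time > min(ev_times) & rec$time < max(ev_times))
  for (i in cens_idx) {
    gap_lo <- max(ev_times[ev_times <= rec$time[i]])
    gap_hi <- min(ev_times[ev_times > rec$time[i]])
    rec3 <- rec
    rec3$time[i] <- (gap_lo + gap_hi) / 2 # still strictly inside the gap
    km3 <- km_estimate(rec3)
    expect_equal(km3$survival[km3$time %in% ev_times],
                 km$survival[km$time %in% ev_times])
  }
})

test_that("with no censoring, KM equals the empirical survival fraction", {
  set.seed(90)
  times <- sample(1:12, 9, replace = TRUE)
  rec <- tibble::tibble(animal_id = paste0("m", 1:9), group = "g",
                        time = times, event = 1L)
  km <- km_estimate(rec)
  expect_equal(km$survival, vapply(km$time, function(t) mean(times > t),
                                   numeric(1)))
})

test_that("log-rank matches the brute-force hypergeometric accumulation", {
  # fully separated arms
  rec <- tibble::tibble(
    animal_id = paste0("m", 1:6),
    group = rep(c("x", "y"), each = 3),
    time = c(2, 3, 4, 20, 21, 22),
    event = 1L
  )
  lr <- logrank_test(rec)
  expect_equal(lr$chi_square,
               brute_logrank_chisq(rec$time, rec$event, rec$group),
               tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))

  set.seed(91)
  done <- 0
  while (done < 50) {
    n <- sample(6:16, 1)
    rec <- tibble::tibble(
      animal_id = paste0("m", seq_len(n)),
      group = sample(c("x", "y"), n, replace = TRUE),
      time = sample(1:12, n, replace = TRUE),
      event = rbinom(n, 1, 0.7)
    )
    if (dplyr::n_distinct(rec$group) < 2 || sum(rec$event) == 0) next
    oracle <- brute_logrank_chisq(rec$time, rec$event, rec$group)
    if (!is.finite(oracle)) next
    expect_equal(logrank_test(rec)$chi_square, oracle, tolerance = 1e-8)
    done <- done + 1
  }
})

test_that("log-rank is symmetric in its arms and handles degenerate input", {
  rec <- tibble::tibble(
    animal_id = paste0("m", 1:8),
    group = rep(c("x", "y"), each = 4),
    time = c(3, 5, 8, 12, 4, 9, 15, 15),
    event = c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L)
  )
  swapped <- dplyr::mutate(rec, group = ifelse(group == "x", "y", "x"))
  expect_equal(logrank_test(rec)$chi_square,
               logrank_test(swapped)$chi_square)
  expect_equal(logrank_test(rec)$p_value, logrank_test(swapped)$p_value)

  ident <- dplyr::mutate(rec, time = rep(c(3, 5, 8, 12), 2),
                         event = rep(c(1L, 1L, 0L, 1L), 2))
  lr0 <- logrank_test(ident)
  expect_lt(lr0$chi_square, 1e-20)
  expect_equal(lr0$p_value, 1)

  one_arm <- rec[rec$group == "x", ]
  expect_error(logrank_test(one_arm), class = "tumorgri_validation_error")
  no_events <- dplyr::mutate(rec, event = 0L)
  expect_error(logrank_test(no_events), class = "tumorgri_degenerate_error")
})
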